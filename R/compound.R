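#' Build a compound parameter set
#'
#' Defines the drug-specific parameters of the permeability-limited model:
#' passive permeability-surface-area products (PS) between adjacent
#' subcompartments, unidirectional transporter clearances on the cell
#' membrane (extracellular <-> intracellular water), metabolic clearances per
#' subcompartment (including the circulating blood pools), and the unbound
#' (fu) and unionized (fi) fractions. Only free, unionized drug permeates
#' passively (pH-partition hypothesis); transporter and metabolic fluxes act
#' on the unbound concentration.
#'
#' Fold parameters are resolved per tissue against its total blood flow Q at
#' build time (the "fold-of-Q" shorthand), e.g. `ps_fold = 0.1` gives every
#' tissue PS products of 0.1 x Q on both the plasma/EW and EW/IW membranes.
#' The blood-cell/plasma membrane within each tissue (`ps_tc_tp`) and within
#' the circulating blood pools (`ps_blood`) defaults to 1000 L/h, i.e.
#' effectively instantaneous plasma/cell equilibration.
#'
#' @param phys a `pbpk_physiology` the folds are resolved against.
#' @param ps_fold fold of Q applied jointly to PS(tp<->ew) and PS(ew<->iw) in
#'   every tissue; may be a single number or a named per-tissue vector.
#' @param ps_tc_tp PS between residual blood cells and residual plasma (L/h,
#'   absolute); single number or named per-tissue vector.
#' @param ps_blood PS between plasma and cells in the arterial, venous, and
#'   portal blood pools (L/h, absolute).
#' @param cl_met_fold named vector of metabolic-clearance folds of Q by
#'   subcompartment, e.g. `c(iw = 1)` or `c(tp = 10)`; subcompartments are
#'   `iw`, `ew`, `tp`, `tc`.
#' @param cl_met_tissues `"all"` or a character vector of tissue names the
#'   metabolic folds apply to (e.g. `"liver"` for hepatic-only metabolism).
#' @param uptake_fold,efflux_fold transporter clearance as a fold of Q,
#'   applied in every tissue (uptake: EW -> IW; efflux: IW -> EW).
#' @param cl_met_blood named vector of absolute metabolic clearances (L/h)
#'   for the circulating blood states `ap`, `ac`, `vp`, `vc`, `pvp`, `pvc`;
#'   default 0.
#' @param fu,fi unbound / unionized fractions; a single number applied to all
#'   subcompartments, or a named vector over
#'   `c("iw","ew","tp","tc","plasma","cells")` (`plasma`/`cells` are the
#'   circulating blood pools).
#' @param overrides optional data.frame of absolute per-tissue values to
#'   override resolved columns; must have a `name` column plus any of
#'   `PS_tp_ew`, `PS_ew_iw`, `PS_tc_tp`, `CL_up`, `CL_eff`, `CL_met_iw`,
#'   `CL_met_ew`, `CL_met_tp`, `CL_met_tc`.
#'
#' @return An object of class `pbpk_compound`: list with `tissues`
#'   (data.frame of per-tissue clearances and PS products in L/h), `blood`
#'   (metabolic clearances of the six blood states), `ps_blood`, `fu`, `fi`.
#'   A compound with every metabolic clearance zero defines a closed system
#'   (mass-conserving); any positive metabolic clearance opens it.
#' @examples
#' phys <- load_physiology()
#' ## PS = Q on both membranes, intracellular metabolism = Q in all tissues
#' cmp <- compound_params(phys, ps_fold = 1, cl_met_fold = c(iw = 1))
#' @export
compound_params <- function(phys,
                            ps_fold = 1,
                            ps_tc_tp = 1000,
                            ps_blood = 1000,
                            cl_met_fold = NULL,
                            cl_met_tissues = "all",
                            uptake_fold = 0,
                            efflux_fold = 0,
                            cl_met_blood = NULL,
                            fu = 1, fi = 1,
                            overrides = NULL) {
  stopifnot(inherits(phys, "pbpk_physiology"))
  ts <- phys$tissues
  n <- nrow(ts)

  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) return(rep(as.numeric(x), n))
    if (is.null(names(x))) stop(what, " must be a scalar or a named vector")
    out <- rep(0, n)
    bad <- setdiff(names(x), ts$name)
    if (length(bad)) stop("unknown tissue in ", what, ": ",
                          paste(bad, collapse = ", "))
    out[match(names(x), ts$name)] <- as.numeric(x)
    out
  }

  df <- data.frame(name = ts$name,
                   PS_tp_ew = expand(ps_fold, "ps_fold") * ts$Q,
                   PS_ew_iw = expand(ps_fold, "ps_fold") * ts$Q,
                   PS_tc_tp = if (length(ps_tc_tp) == 1 && is.null(names(ps_tc_tp)))
                     rep(ps_tc_tp, n) else expand(ps_tc_tp, "ps_tc_tp"),
                   CL_up  = expand(uptake_fold, "uptake_fold") * ts$Q,
                   CL_eff = expand(efflux_fold, "efflux_fold") * ts$Q,
                   CL_met_iw = 0, CL_met_ew = 0, CL_met_tp = 0, CL_met_tc = 0,
                   stringsAsFactors = FALSE)
  rownames(df) <- df$name

  if (!is.null(cl_met_fold)) {
    if (is.null(names(cl_met_fold)) ||
        !all(names(cl_met_fold) %in% .subcomps))
      stop("cl_met_fold must be named by subcompartment (iw, ew, tp, tc)")
    target <- if (identical(cl_met_tissues, "all")) ts$name else cl_met_tissues
    bad <- setdiff(target, ts$name)
    if (length(bad)) stop("unknown tissue in cl_met_tissues: ",
                          paste(bad, collapse = ", "))
    for (sub in names(cl_met_fold)) {
      col <- paste0("CL_met_", sub)
      df[target, col] <- cl_met_fold[[sub]] * ts[target, "Q"]
    }
  }

  blood <- stats::setNames(rep(0, length(.blood_states)), .blood_states)
  if (!is.null(cl_met_blood)) {
    bad <- setdiff(names(cl_met_blood), .blood_states)
    if (length(bad)) stop("unknown blood state in cl_met_blood: ",
                          paste(bad, collapse = ", "))
    blood[names(cl_met_blood)] <- as.numeric(cl_met_blood)
  }

  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides), "name" %in% names(overrides))
    for (col in setdiff(names(overrides), "name")) {
      if (!col %in% names(df)) stop("unknown override column: ", col)
      df[overrides$name, col] <- overrides[[col]]
    }
  }

  frac <- function(x, what) {
    keys <- c(.subcomps, "plasma", "cells")
    if (length(x) == 1 && is.null(names(x)))
      x <- stats::setNames(rep(as.numeric(x), length(keys)), keys)
    if (!all(keys %in% names(x)))
      stop(what, " must be a scalar or named over ",
           paste(keys, collapse = ", "))
    x <- x[keys]
    if (any(x < 0 | x > 1)) stop(what, " fractions must lie in [0, 1]")
    x
  }

  num <- as.matrix(df[, -1])
  if (any(!is.finite(num)) || any(num < 0))
    stop("all PS products and clearances must be finite and nonnegative")
  if (any(blood < 0)) stop("blood metabolic clearances must be nonnegative")
  if (ps_blood < 0) stop("ps_blood must be nonnegative")

  structure(list(tissues = df, blood = blood, ps_blood = ps_blood,
                 fu = frac(fu, "fu"), fi = frac(fi, "fi")),
            class = "pbpk_compound")
}

#' Is a compound closed-system?
#'
#' A compound defines a closed (mass-conserving) system when every metabolic
#' clearance, in tissues and blood, is zero.
#'
#' @param compound a `pbpk_compound`.
#' @return logical.
#' @export
is_closed_system <- function(compound) {
  stopifnot(inherits(compound, "pbpk_compound"))
  met <- as.matrix(compound$tissues[, paste0("CL_met_", .subcomps)])
  all(met == 0) && all(compound$blood == 0)
}

#' @export
print.pbpk_compound <- function(x, ...) {
  cat(sprintf("pbpk_compound: %d tissues, %s system\n",
              nrow(x$tissues),
              if (is_closed_system(x)) "closed" else "open"))
  invisible(x)
}
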