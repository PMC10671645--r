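#' @keywords internal
"_PACKAGE"

## Canonical tissue/compartment naming used throughout the package.
## Tissue order is alphabetical and fixed so that state indices, CSVs and
## closed-form oracles always agree.

#' Canonical tissue names
#'
#' The 12 tissues of the whole-body model, in the fixed (alphabetical) order
#' used for state indexing everywhere in the package.
#'
#' @return Character vector of length 12.
#' @export
pbpk_tissues <- function() {
  c("adipose", "bone", "brain", "gut", "heart", "kidney",
    "liver", "lung", "muscle", "pancreas", "skin", "spleen")
}

## tissues draining into the portal vein, and tissues draining directly to
## venous blood; lung is perfused by venous blood and drains to arterial blood
.splanchnic <- c("gut", "pancreas", "spleen")
.subcomps <- c("iw", "ew", "tp", "tc")
.blood_states <- c("ap", "ac", "vp", "vc", "pvp", "pvc")

.venous_draining <- function(tissues) setdiff(tissues, c(.splanchnic, "lung"))
.arterial_perfused <- function(tissues) setdiff(tissues, c("liver", "lung"))

#' Construct a validated body physiology
#'
#' Assembles tissue volumes, subcompartment splits and the blood-flow network
#' into a `pbpk_physiology` object. Residual blood within each tissue is split
#' into blood-cell (TC) and plasma (TP) subcompartments by the hematocrit, and
#' every blood flow is split into plasma and blood-cell streams the same way
#' (flowing blood is treated as homogeneous, so the cell fraction of flow
#' equals the cell fraction of volume).
#'
#' The circulation topology is fixed: pancreas, spleen and gut drain into the
#' portal vein; portal vein plus hepatic artery perfuse the liver; liver and
#' all remaining tissues drain into venous blood; venous blood perfuses the
#' lung; the lung drains into arterial blood.
#'
#' @param tissues data.frame with columns `name`, `V_total` (L),
#'   `V_res` (residual blood, L), `V_ew`, `V_iw` (L), `Q` (total tissue blood
#'   flow, L/h). Must contain at least `liver` and `lung`; any tissue of
#'   [pbpk_tissues()] may be present (reduced toy bodies are allowed).
#' @param v_arterial,v_venous,v_portal blood-pool volumes (L).
#' @param hct hematocrit (fraction of blood volume that is cells).
#' @param density body density (kg/L); body weight is total volume times
#'   density. The reference parameterization uses 1 kg/L.
#' @param tol tolerance for the flow-balance checks (L/h).
#'
#' @return An object of class `pbpk_physiology`: a list with elements
#'   `tissues` (data.frame with per-tissue volumes `V_total`, `V_res`, `V_iw`,
#'   `V_ew`, `V_tp`, `V_tc` and flows `Q`, `Q_tp`, `Q_tc`), `blood` (named
#'   volumes `V_ap`, `V_ac`, `V_vp`, `V_vc`, `V_pvp`, `V_pvc`), `hct`, `bw`,
#'   `co`, and derived network flows (`q_ha_p`, `q_ha_c`, `q_pv_p`, `q_pv_c`,
#'   `q_pvp`, `q_pvc`, `q_vp`, `q_vc`).
#' @seealso [load_physiology()], [validate_flow_balance()]
#' @export
body_physiology <- function(tissues, v_arterial, v_venous, v_portal,
                            hct = 0.45, density = 1, tol = 1e-6) {
  stopifnot(is.data.frame(tissues),
            all(c("name", "V_total", "V_res", "V_ew", "V_iw", "Q") %in%
                  names(tissues)))
  unknown <- setdiff(tissues$name, pbpk_tissues())
  ok_generic <- grepl("^tissue[0-9]+$", unknown)
  if (any(!ok_generic))
    stop("unknown tissue name(s): ", paste(unknown[!ok_generic], collapse = ", "))
  if (!all(c("liver", "lung") %in% tissues$name))
    stop("physiology must include at least liver and lung")
  if (anyDuplicated(tissues$name)) stop("duplicated tissue names")

  num_cols <- c("V_total", "V_res", "V_ew", "V_iw", "Q")
  if (any(!is.finite(as.matrix(tissues[num_cols]))) ||
      any(as.matrix(tissues[num_cols]) < 0))
    stop("tissue volumes and flows must be finite and nonnegative")
  bad <- abs(tissues$V_res + tissues$V_ew + tissues$V_iw - tissues$V_total) > 1e-9
  if (any(bad))
    stop("subcompartment volumes do not sum to total volume for: ",
         paste(tissues$name[bad], collapse = ", "))
  if (any(c(v_arterial, v_venous, v_portal) < 0))
    stop("blood-pool volumes must be nonnegative")
  if (hct <= 0 || hct >= 1) stop("hematocrit must lie in (0, 1)")

  ## order tissues canonically (known tissues first in canonical order,
  ## generic toy tissues after, by name)
  known <- intersect(pbpk_tissues(), tissues$name)
  generic <- sort(setdiff(tissues$name, known))
  tissues <- tissues[match(c(known, generic), tissues$name), , drop = FALSE]
  rownames(tissues) <- tissues$name

  ## hematocrit split of residual blood volume and of every blood flow
  tissues$V_tc <- hct * tissues$V_res
  tissues$V_tp <- (1 - hct) * tissues$V_res
  tissues$Q_tc <- hct * tissues$Q
  tissues$Q_tp <- (1 - hct) * tissues$Q

  blood <- c(V_ap  = (1 - hct) * v_arterial, V_ac  = hct * v_arterial,
             V_vp  = (1 - hct) * v_venous,   V_vc  = hct * v_venous,
             V_pvp = (1 - hct) * v_portal,   V_pvc = hct * v_portal)

  spl <- intersect(.splanchnic, tissues$name)
  q_pv   <- sum(tissues[spl, "Q"])
  q_liver <- tissues["liver", "Q"]
  if (q_liver < q_pv - tol)
    stop("flow balance violated (liver inflow): liver flow ", q_liver,
         " L/h is less than total splanchnic outflow ", q_pv,
         " L/h (hepatic artery flow would be negative)")
  q_ha <- q_liver - q_pv

  ven <- .venous_draining(tissues$name)
  co <- sum(tissues[ven, "Q"])
  if (abs(tissues["lung", "Q"] - co) > tol)
    stop("flow balance violated (venous return vs cardiac output): ",
         "lung flow ", tissues["lung", "Q"], " L/h but venous return ",
         co, " L/h")

  bw <- density * (sum(tissues$V_total) + v_arterial + v_venous + v_portal)

  phys <- structure(list(
    tissues = tissues,
    blood = blood,
    hct = hct,
    density = density,
    bw = bw,
    co = co,
    q_ha_p = (1 - hct) * q_ha, q_ha_c = hct * q_ha,
    q_pv_p = (1 - hct) * q_pv, q_pv_c = hct * q_pv,
    q_pvp  = (1 - hct) * q_pv, q_pvc  = hct * q_pv,
    q_vp   = (1 - hct) * co,   q_vc   = hct * co
  ), class = "pbpk_physiology")

  rep <- validate_flow_balance(phys)
  if (any(abs(rep$residual) > tol))
    stop("flow balance violated: ",
         paste(sprintf("%s (residual %.3g)",
                       rep$equation[abs(rep$residual) > tol],
                       rep$residual[abs(rep$residual) > tol]),
               collapse = "; "))
  phys
}

#' Load the reference physiology table
#'
#' Reads a physiology CSV (columns `tissue`, `V_total_L`,
#' `V_residual_blood_L`, `V_ew_L`, `V_iw_L`, `Q_blood_L_per_h`, with rows
#' `arterial_blood`, `venous_blood`, `portal_vein` carrying the blood-pool
#' volumes) and returns a validated [body_physiology()] object.
#'
#' The default table is the package's 70 kg / 300 L/h human reference
#' parameterization, assembled from standard reference-man tissue volumes and
#' blood-flow fractions with residual-blood fractions in the range reported
#' for exsanguinated rat tissues, then balanced exactly to a 70 L total volume
#' (density 1 kg/L, so 70 kg) and a 300 L/h cardiac output. Residual blood is
#' split 45%/55% into blood cells/plasma (hematocrit 0.45).
#'
#' If print rounding in a user-supplied table leaves the total volume within
#' `repair_tol` of the nominal body weight, the muscle intracellular volume is
#' rescaled (muscle is the designated slack tissue) to restore exact balance,
#' with a message reporting the adjustment.
#'
#' @param path path to the CSV; `NULL` uses the shipped reference table.
#' @param hct hematocrit used for all volume and flow splits.
#' @param target_bw nominal body weight (kg) used only for the rounding
#'   repair; `NULL` disables the repair.
#' @param repair_tol maximum discrepancy (L) repaired by rescaling muscle.
#' @return A `pbpk_physiology` object.
#' @examples
#' phys <- load_physiology()
#' phys$bw   # 70 kg
#' phys$co   # 300 L/h
#' @export
load_physiology <- function(path = NULL, hct = 0.45, target_bw = 70,
                            repair_tol = 0.05) {
  if (is.null(path))
    path <- system.file("extdata", "physiology_human70_synthetic.csv",
                        package = "permpbpk", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "V_total_L", "V_residual_blood_L", "V_ew_L", "V_iw_L",
            "Q_blood_L_per_h")
  if (!all(need %in% names(tab)))
    stop("physiology table must have columns: ", paste(need, collapse = ", "))

  pools <- c("arterial_blood", "venous_blood", "portal_vein")
  miss <- setdiff(pools, tab$tissue)
  if (length(miss))
    stop("physiology table is missing blood-pool row(s): ",
         paste(miss, collapse = ", "))
  pool_v <- stats::setNames(tab$V_total_L[match(pools, tab$tissue)], pools)

  tis <- tab[!tab$tissue %in% pools, , drop = FALSE]
  miss <- setdiff(pbpk_tissues(), tis$tissue)
  if (length(miss))
    stop("physiology table is missing tissue(s): ", paste(miss, collapse = ", "))

  df <- data.frame(name = tis$tissue,
                   V_total = tis$V_total_L,
                   V_res = tis$V_residual_blood_L,
                   V_ew = tis$V_ew_L,
                   V_iw = tis$V_iw_L,
                   Q = tis$Q_blood_L_per_h,
                   stringsAsFactors = FALSE)

  if (!is.null(target_bw) && "muscle" %in% df$name) {
    total <- sum(df$V_total) + sum(pool_v)
    off <- target_bw - total
    if (off != 0 && abs(off) <= repair_tol) {
      i <- which(df$name == "muscle")
      df$V_total[i] <- df$V_total[i] + off
      df$V_iw[i] <- df$V_iw[i] + off
      message(sprintf(
        "physiology total volume %.6f L rounded; muscle rescaled by %+.6f L to match %g kg",
        total, off, target_bw))
    } else if (abs(off) > repair_tol) {
      stop(sprintf(
        "total volume %.6f L deviates from nominal body weight %g kg by more than %g L",
        total, target_bw, repair_tol))
    }
  }

  body_physiology(df,
                  v_arterial = pool_v[["arterial_blood"]],
                  v_venous = pool_v[["venous_blood"]],
                  v_portal = pool_v[["portal_vein"]],
                  hct = hct)
}

#' Report flow- and volume-balance residuals
#'
#' Evaluates every conservation equation of the circulation network and
#' returns the residual of each; a valid physiology has all residuals at
#' (numerical) zero. This reports only — [body_physiology()] raises on
#' violations at construction.
#'
#' The equations checked, per plasma/blood-cell stream: liver inflow equals
#' hepatic artery plus portal vein; portal-vein inflow equals the splanchnic
#' (pancreas + spleen + gut) outflows; venous return equals the sum of the
#' directly draining tissues; venous plasma plus blood-cell return equals the
#' cardiac output; lung flow equals cardiac output; and the volume balance,
#' total volume = BW / density.
#'
#' @param phys a `pbpk_physiology` object.
#' @return data.frame with columns `equation` and `residual`.
#' @export
validate_flow_balance <- function(phys) {
  stopifnot(inherits(phys, "pbpk_physiology"))
  ts <- phys$tissues
  spl <- intersect(.splanchnic, ts$name)
  ven <- .venous_draining(ts$name)
  res <- c(
    liver_plasma_inflow = ts["liver", "Q_tp"] - (phys$q_ha_p + phys$q_pv_p),
    liver_cell_inflow   = ts["liver", "Q_tc"] - (phys$q_ha_c + phys$q_pv_c),
    portal_plasma       = phys$q_pvp - sum(ts[spl, "Q_tp"]),
    portal_cells        = phys$q_pvc - sum(ts[spl, "Q_tc"]),
    venous_plasma       = phys$q_vp - sum(ts[ven, "Q_tp"]),
    venous_cells        = phys$q_vc - sum(ts[ven, "Q_tc"]),
    cardiac_output      = phys$q_vp + phys$q_vc - phys$co,
    lung_perfusion      = ts["lung", "Q"] - phys$co,
    volume_balance      = sum(ts$V_total) + sum(phys$blood) -
                            phys$bw / phys$density
  )
  data.frame(equation = names(res), residual = unname(res),
             stringsAsFactors = FALSE)
}

#' @export
print.pbpk_physiology <- function(x, ...) {
  cat(sprintf("pbpk_physiology: %d tissues, BW %.4g kg, CO %.4g L/h, Hct %.2f\n",
              nrow(x$tissues), x$bw, x$co, x$hct))
  cat(sprintf("  blood pools (L): arterial %.3g, venous %.3g, portal %.3g\n",
              x$blood[["V_ap"]] + x$blood[["V_ac"]],
              x$blood[["V_vp"]] + x$blood[["V_vc"]],
              x$blood[["V_pvp"]] + x$blood[["V_pvc"]]))
  invisible(x)
}
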