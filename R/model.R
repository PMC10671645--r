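## Flux laws and assembly of the whole-body system as a linear ODE on
## subcompartment concentrations.

#' Passive transmembrane flux
#'
#' Bidirectional passive flux across a membrane. Under the pH-partition
#' hypothesis only unbound, unionized drug permeates, so the driving force is
#' the difference of the free, unionized concentrations on the two sides:
#' `PS * (C_a*fu_a*fi_a - C_b*fu_b*fi_b)` (mg/h, positive a -> b). The flux
#' is antisymmetric under swapping sides.
#'
#' @param ps permeability-surface-area product (L/h), nonnegative.
#' @param c_a,c_b concentrations on side a and b (mg/L).
#' @param fu_a,fu_b unbound fractions.
#' @param fi_a,fi_b unionized fractions.
#' @return flux (mg/h), positive from a to b.
#' @export
passive_flux <- function(ps, c_a, fu_a = 1, fi_a = 1, c_b = 0, fu_b = 1,
                         fi_b = 1) {
  if (any(ps < 0)) stop("PS must be nonnegative")
  ps * (c_a * fu_a * fi_a - c_b * fu_b * fi_b)
}

#' Active transporter flux
#'
#' Unidirectional carrier-mediated flux, `CL * C_source * fu_source` (mg/h).
#' Uptake transporters carry drug from extracellular to intracellular water
#' (source EW); efflux transporters carry it back (source IW). Note the flux
#' depends on the unbound fraction only, not on ionization.
#'
#' @param cl transporter clearance (L/h), nonnegative.
#' @param c_source source-side concentration (mg/L).
#' @param fu_source source-side unbound fraction.
#' @return flux (mg/h), nonnegative for nonnegative inputs.
#' @export
active_transport_flux <- function(cl, c_source, fu_source = 1) {
  if (any(cl < 0)) stop("transporter clearance must be nonnegative")
  cl * c_source * fu_source
}

#' Metabolic flux
#'
#' First-order metabolic elimination within a subcompartment,
#' `CL_met * C * fu` (mg/h). As with transport, the unbound fraction alone
#' scales the flux.
#'
#' @param cl_met metabolic clearance (L/h), nonnegative.
#' @param conc concentration (mg/L).
#' @param fu unbound fraction.
#' @return flux (mg/h).
#' @export
metabolic_flux <- function(cl_met, conc, fu = 1) {
  if (any(cl_met < 0)) stop("metabolic clearance must be nonnegative")
  cl_met * conc * fu
}

#' Traditional perfusion-limited steady-state comparator
#'
#' The classical well-stirred derivation for an isolated perfusion-limited
#' tissue with intrinsic clearance: the extraction ratio is
#' `ER = CL_int / (Q + CL_int)`, the steady-state partition coefficient is
#' `Kpss = Kp * (1 - ER)`, and the body-level
#' `Vdss = V_plasma + sum(V_tissue * Kp * (1 - ER))`, normalized by body
#' weight when `bw` is supplied. This is the reference theory the
#' permeability-limited model is contrasted against; it predicts that tissue
#' metabolism always lowers Kpss and Vdss.
#'
#' @param kp tissue/plasma partition coefficient(s) (dimensionless).
#' @param q tissue blood flow(s) (L/h), positive.
#' @param cl_int tissue intrinsic clearance(s) (L/h), nonnegative.
#' @param v_tissue tissue volume(s) (L).
#' @param v_plasma plasma volume (L).
#' @param bw body weight (kg); if `NULL` the Vdss is returned in L.
#' @return list with `er`, `kpss` (per tissue) and `vdss`.
#' @export
reference_perfusion_model <- function(kp, q, cl_int = 0, v_tissue,
                                      v_plasma, bw = NULL) {
  if (any(q <= 0)) stop("tissue blood flow must be positive")
  if (any(cl_int < 0)) stop("intrinsic clearance must be nonnegative")
  er <- cl_int / (q + cl_int)
  kpss <- kp * (1 - er)
  vdss <- v_plasma + sum(v_tissue * kpss)
  if (!is.null(bw)) vdss <- vdss / bw
  list(er = er, kpss = kpss, vdss = vdss)
}

#' State names of the assembled system
#'
#' @param phys a `pbpk_physiology`.
#' @return character vector: for each tissue (canonical order) the states
#'   `<tissue>_iw`, `_ew`, `_tp`, `_tc`, followed by the blood states
#'   `ap`, `ac`, `vp`, `vc`, `pvp`, `pvc`.
#' @export
pbpk_state_names <- function(phys) {
  c(as.vector(t(outer(phys$tissues$name, .subcomps, paste, sep = "_"))),
    .blood_states)
}

#' Assemble the whole-body linear system
#'
#' Builds the full set of subcompartment mass balances as a linear
#' time-invariant system `dC/dt = A C + forcing` on concentrations. For the
#' 12-tissue reference body this is a 54-state system (12 tissues x
#' \{IW, EW, TP, TC\} + 3 blood pools x \{plasma, cells\}).
#'
#' Each tissue couples its four subcompartments by passive PS fluxes
#' (TC<->TP, TP<->EW, EW<->IW), transporters on the cell membrane (EW<->IW)
#' and metabolism in any subcompartment; tissue plasma/cell subcompartments
#' exchange with the perfusing blood at the plasma/cell flow rates. Arterial
#' blood perfuses the typical tissues; pancreas, spleen and gut drain to the
#' portal vein; portal vein plus hepatic artery perfuse the liver; liver and
#' the remaining tissues drain to venous blood; venous blood perfuses the
#' lung, which drains to arterial blood.
#'
#' Mass leaves the system only through metabolism: for every state j the
#' volume-weighted column sum `sum_i V_i A[i,j]` equals `-CL_met(j)*fu(j)`,
#' and is exactly zero in a closed system (where A then has eigenvalue 0 with
#' a uniform right eigenvector — the equilibrium of even distribution).
#'
#' @param phys a `pbpk_physiology`.
#' @param compound a `pbpk_compound` built against the same tissue set.
#' @return An object of class `pbpk_system`: list with `A` (rate matrix,
#'   1/h), `V` (state volumes, L), `states` (names), `index` (named
#'   positions), `cl_met` and `fu`, `fi` per state, `input` (unit mass-input
#'   vectors for the iv and po routes), `phys`, `compound`.
#' @export
assemble_system <- function(phys, compound) {
  stopifnot(inherits(phys, "pbpk_physiology"),
            inherits(compound, "pbpk_compound"))
  ts <- phys$tissues
  cp <- compound$tissues
  if (!identical(sort(ts$name), sort(cp$name)))
    stop("tissue sets of physiology and compound do not match")
  cp <- cp[ts$name, , drop = FALSE]

  states <- pbpk_state_names(phys)
  n <- length(states)
  idx <- stats::setNames(seq_len(n), states)
  A <- matrix(0, n, n, dimnames = list(states, states))

  V <- numeric(n)
  names(V) <- states
  for (t in ts$name) {
    V[paste0(t, "_iw")] <- ts[t, "V_iw"]
    V[paste0(t, "_ew")] <- ts[t, "V_ew"]
    V[paste0(t, "_tp")] <- ts[t, "V_tp"]
    V[paste0(t, "_tc")] <- ts[t, "V_tc"]
  }
  V[.blood_states] <- phys$blood[paste0("V_", .blood_states)]
  if (any(V <= 0))
    stop("all state volumes must be positive; zero volume for: ",
         paste(states[V <= 0], collapse = ", "))

  fu <- compound$fu; fi <- compound$fi
  fu_state <- numeric(n); fi_state <- numeric(n); cl_met <- numeric(n)
  names(fu_state) <- names(fi_state) <- names(cl_met) <- states
  for (t in ts$name) for (s in .subcomps) {
    fu_state[paste0(t, "_", s)] <- fu[[s]]
    fi_state[paste0(t, "_", s)] <- fi[[s]]
    cl_met[paste0(t, "_", s)] <- cp[t, paste0("CL_met_", s)]
  }
  plasma_pools <- c("ap", "vp", "pvp"); cell_pools <- c("ac", "vc", "pvc")
  fu_state[plasma_pools] <- fu[["plasma"]]; fu_state[cell_pools] <- fu[["cells"]]
  fi_state[plasma_pools] <- fi[["plasma"]]; fi_state[cell_pools] <- fi[["cells"]]
  cl_met[.blood_states] <- compound$blood[.blood_states]

  a <- fu_state * fi_state   # passive activity coefficient per state

  ## helper: passive exchange between states i and j with product ps
  add_passive <- function(i, j, ps) {
    A[i, j] <<- A[i, j] + ps * a[j] / V[i]
    A[i, i] <<- A[i, i] - ps * a[i] / V[i]
    A[j, i] <<- A[j, i] + ps * a[i] / V[j]
    A[j, j] <<- A[j, j] - ps * a[j] / V[j]
  }
  ## helper: unidirectional clearance from state i to state j (fu only)
  add_transport <- function(i, j, cl) {
    A[j, i] <<- A[j, i] + cl * fu_state[i] / V[j]
    A[i, i] <<- A[i, i] - cl * fu_state[i] / V[i]
  }
  ## helper: perfusion inflow j -> i at flow q with washout from i
  add_perfusion <- function(i, j, q) {
    A[i, j] <<- A[i, j] + q / V[i]
    A[i, i] <<- A[i, i] - q / V[i]
  }

  for (t in ts$name) {
    iw <- idx[paste0(t, "_iw")]; ew <- idx[paste0(t, "_ew")]
    tp <- idx[paste0(t, "_tp")]; tc <- idx[paste0(t, "_tc")]
    add_passive(ew, iw, cp[t, "PS_ew_iw"])
    add_passive(tp, ew, cp[t, "PS_tp_ew"])
    add_passive(tc, tp, cp[t, "PS_tc_tp"])
    add_transport(ew, iw, cp[t, "CL_up"])
    add_transport(iw, ew, cp[t, "CL_eff"])

    if (t == "lung") {
      add_perfusion(tp, idx["vp"], phys$q_vp)
      add_perfusion(tc, idx["vc"], phys$q_vc)
    } else if (t == "liver") {
      ## two inflows, one washout at the summed flow
      A[tp, idx["ap"]] <- A[tp, idx["ap"]] + phys$q_ha_p / V[tp]
      A[tp, idx["pvp"]] <- A[tp, idx["pvp"]] + phys$q_pv_p / V[tp]
      A[tp, tp] <- A[tp, tp] - ts[t, "Q_tp"] / V[tp]
      A[tc, idx["ac"]] <- A[tc, idx["ac"]] + phys$q_ha_c / V[tc]
      A[tc, idx["pvc"]] <- A[tc, idx["pvc"]] + phys$q_pv_c / V[tc]
      A[tc, tc] <- A[tc, tc] - ts[t, "Q_tc"] / V[tc]
    } else {
      add_perfusion(tp, idx["ap"], ts[t, "Q_tp"])
      add_perfusion(tc, idx["ac"], ts[t, "Q_tc"])
    }
  }

  ## portal vein collects the splanchnic outflows
  spl <- intersect(.splanchnic, ts$name)
  for (t in spl) {
    A[idx["pvp"], idx[paste0(t, "_tp")]] <-
      A[idx["pvp"], idx[paste0(t, "_tp")]] + ts[t, "Q_tp"] / V[idx["pvp"]]
    A[idx["pvc"], idx[paste0(t, "_tc")]] <-
      A[idx["pvc"], idx[paste0(t, "_tc")]] + ts[t, "Q_tc"] / V[idx["pvc"]]
  }
  A[idx["pvp"], idx["pvp"]] <- A[idx["pvp"], idx["pvp"]] -
    phys$q_pvp / V[idx["pvp"]]
  A[idx["pvc"], idx["pvc"]] <- A[idx["pvc"], idx["pvc"]] -
    phys$q_pvc / V[idx["pvc"]]

  ## venous blood collects the directly draining tissues
  for (t in .venous_draining(ts$name)) {
    A[idx["vp"], idx[paste0(t, "_tp")]] <-
      A[idx["vp"], idx[paste0(t, "_tp")]] + ts[t, "Q_tp"] / V[idx["vp"]]
    A[idx["vc"], idx[paste0(t, "_tc")]] <-
      A[idx["vc"], idx[paste0(t, "_tc")]] + ts[t, "Q_tc"] / V[idx["vc"]]
  }
  A[idx["vp"], idx["vp"]] <- A[idx["vp"], idx["vp"]] - phys$q_vp / V[idx["vp"]]
  A[idx["vc"], idx["vc"]] <- A[idx["vc"], idx["vc"]] - phys$q_vc / V[idx["vc"]]

  ## arterial blood is fed by the lung outflow
  add_perfusion(idx["ap"], idx[paste0("lung_tp")], phys$q_vp)
  add_perfusion(idx["ac"], idx[paste0("lung_tc")], phys$q_vc)

  ## plasma/cell exchange within the blood pools
  add_passive(idx["vp"], idx["vc"], compound$ps_blood)
  add_passive(idx["ap"], idx["ac"], compound$ps_blood)
  add_passive(idx["pvp"], idx["pvc"], compound$ps_blood)

  ## metabolism everywhere
  for (i in seq_len(n))
    A[i, i] <- A[i, i] - cl_met[i] * fu_state[i] / V[i]

  input <- list(
    iv = stats::setNames(as.numeric(states == "vp"), states),
    po = stats::setNames(as.numeric(states == "gut_iw"), states)
  )
  if (!"gut" %in% ts$name) input$po <- NULL

  structure(list(A = A, V = V, states = states, index = idx,
                 cl_met = cl_met, fu = fu_state, fi = fi_state,
                 input = input, phys = phys, compound = compound),
            class = "pbpk_system")
}

#' @export
print.pbpk_system <- function(x, ...) {
  cat(sprintf("pbpk_system: %d states (%d tissues + %d blood states), %s\n",
              length(x$states), nrow(x$phys$tissues), length(.blood_states),
              if (is_closed_system(x$compound)) "closed (mass-conserving)"
              else "open (metabolizing)"))
  invisible(x)
}
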