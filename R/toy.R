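## Miniature randomized physiologies for fast, exhaustive testing.

#' Generate a miniature balanced physiology
#'
#' Builds a reduced body — liver, lung, gut plus `n_generic` generic tissues
#' and the three blood pools — with randomized volumes and flows that obey
#' every balance equation of the full model by construction (the gut drains
#' through the portal vein into the liver, so the portal/liver equations are
#' always exercised). Deterministic given `seed`; the global random state is
#' left untouched.
#'
#' @param n_generic number of generic tissues (named `tissue1`, ...), >= 1.
#' @param seed integer seed; `NULL` uses the current random state.
#' @param hct hematocrit.
#' @return A `pbpk_physiology` with `3 + n_generic` tissues.
#' @export
make_toy_body <- function(n_generic = 1, seed = NULL, hct = 0.45) {
  if (n_generic < 1) stop("n_generic must be at least 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  ru <- function(lo, hi) stats::runif(1, lo, hi)

  gen <- paste0("tissue", seq_len(n_generic))
  names <- c("gut", "liver", "lung", gen)

  v_total <- c(gut = ru(0.5, 2), liver = ru(1, 3), lung = ru(0.3, 1),
               stats::setNames(stats::runif(n_generic, 0.5, 8), gen))
  res_frac <- stats::setNames(stats::runif(length(names), 0.02, 0.3), names)
  ew_frac <- stats::setNames(stats::runif(length(names), 0.1, 0.4), names)

  q_gut <- ru(20, 60)
  q_ha <- ru(5, 20)
  q_gen <- stats::setNames(stats::runif(n_generic, 5, 60), gen)
  q_liver <- q_ha + q_gut
  co <- q_liver + sum(q_gen)
  q <- c(gut = q_gut, liver = q_liver, lung = co, q_gen)

  v_res <- res_frac * v_total
  v_ew <- ew_frac * (v_total - v_res)
  v_iw <- v_total - v_res - v_ew

  df <- data.frame(name = names,
                   V_total = v_total[names], V_res = v_res[names],
                   V_ew = v_ew[names], V_iw = v_iw[names],
                   Q = q[names], stringsAsFactors = FALSE)
  body_physiology(df,
                  v_arterial = ru(0.5, 2),
                  v_venous = ru(1, 4),
                  v_portal = ru(0.1, 0.5),
                  hct = hct)
}
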