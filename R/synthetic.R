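#' Synthetic observation table from a simulated trajectory
#'
#' Emulates the study's measurement structure: daily pre-feeding grab
#' samples of VFA concentrations, pH and volatile-solids biomass, optionally
#' a dense 24-hour VFA series, and methanogen composition. Concentrations
#' receive multiplicative lognormal noise (given as a coefficient of
#' variation), pH additive Gaussian noise. Fully reproducible from `seed`.
#'
#' @param traj an `adm1_trajectory`
#' @param times sampling times, days (default: daily from day 1)
#' @param dense_window optional `c(start, end)` of a dense series, days
#' @param dense_dt spacing of the dense series, days
#' @param quantities subset of
#'   `c("VFA_total","VFA_ac","VFA_pro","VFA_bu","pH","VS_biomass",
#'   "f_sarcina","CH4_rate")`
#' @param cv coefficient of variation of concentration noise
#' @param ph_sd additive standard deviation of pH noise
#' @param seed integer seed
#' @return data.frame with columns `time`, `quantity`, `value`, `noise_sd`
#' @export
generate_observations <- function(traj,
                                  times = seq(1, floor(max(traj$time))),
                                  dense_window = NULL, dense_dt = 1 / 24,
                                  quantities = c("VFA_total", "VFA_ac",
                                                 "VFA_pro", "VFA_bu", "pH",
                                                 "VS_biomass", "f_sarcina",
                                                 "CH4_rate"),
                                  cv = 0.10, ph_sd = 0.05, seed = 1) {
  if (any(times < min(traj$time) | times > max(traj$time)))
    stop("sampling schedule outside the simulated horizon")
  if (!is.null(dense_window)) {
    dense <- seq(dense_window[1], dense_window[2], by = dense_dt)
    if (any(dense < min(traj$time) | dense > max(traj$time)))
      stop("dense window outside the simulated horizon")
    times <- sort(unique(c(times, dense)))
  }
  cols <- c(VFA_total = "vfa_total", VFA_ac = "S_ac", VFA_pro = "S_pro",
            VFA_bu = "S_bu", pH = "pH", VS_biomass = "biomass_vs",
            f_sarcina = "f_sarcina", CH4_rate = "q_ch4_norm")
  quantities <- match.arg(quantities, names(cols), several.ok = TRUE)
  interp <- function(col) stats::approx(traj$time, traj[[col]],
                                        xout = times, rule = 2)$y
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  rows <- lapply(quantities, function(qt) {
    truth <- interp(cols[[qt]])
    if (qt == "pH") {
      val <- truth + stats::rnorm(length(truth), 0, ph_sd)
      nsd <- ph_sd
    } else if (qt == "f_sarcina") {
      val <- pmin(1, pmax(0, truth * stats::rlnorm(length(truth), -sdlog^2 / 2, sdlog)))
      nsd <- cv
    } else {
      val <- truth * stats::rlnorm(length(truth), -sdlog^2 / 2, sdlog)
      nsd <- cv
    }
    data.frame(time = times, quantity = qt, value = val, noise_sd = nsd)
  })
  do.call(rbind, rows)
}

#' Synthetic community profiles
#'
#' Generates relative-abundance profiles with assigned operon copy numbers
#' and order labels, for exercising the community analytics without
#' sequence data. `"dirichlet"` draws a random profile with concentration
#' `alpha`; `"geometric"` builds the deterministic series `ratio^(i-1)`
#' (renormalized); `"uniform"` is perfectly even.
#'
#' @param n_taxa number of taxa
#' @param distribution `"dirichlet"`, `"geometric"`, or `"uniform"`
#' @param alpha Dirichlet concentration parameter
#' @param ratio geometric decay ratio in `(0, 1)`
#' @param seed integer seed
#' @return a [community_profile()] (filenames and labels are synthetic)
#' @export
generate_community_profiles <- function(n_taxa,
                                        distribution = c("dirichlet",
                                                         "geometric",
                                                         "uniform"),
                                        alpha = 1, ratio = 0.5, seed = 1) {
  if (n_taxa < 1) stop("n_taxa must be at least 1")
  distribution <- match.arg(distribution)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- switch(distribution,
    dirichlet = { g <- stats::rgamma(n_taxa, alpha); g / sum(g) },
    geometric = { if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0,1)")
                  w <- ratio^(seq_len(n_taxa) - 1); w / sum(w) },
    uniform = rep(1 / n_taxa, n_taxa))
  orders <- sample(c(MRTA_ORDERS, "Methanosarcinales", "Methanomicrobiales"),
                   n_taxa, replace = TRUE)
  cn <- sample(1:7, n_taxa, replace = TRUE)
  community_profile(paste0("OTU_", seq_len(n_taxa)), p,
                    copy_number = cn, order = orders)
}
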