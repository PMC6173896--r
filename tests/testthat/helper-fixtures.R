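## Shared simulation fixtures, computed once per test run and cached.
## The Experiment-1 trajectories with and without the day-64 disturbance
## are identical up to day 64, so only the disturbed (78-day) run is
## simulated and the training-phase view is a truncation of it.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

exp1_run <- function(regime = c("conti", "disco"), disturbed = FALSE) {
  regime <- match.arg(regime)
  full <- fixture(paste0("exp1_", regime, "_dist"), function() {
    sc <- preset_scenario(paste0("exp1_", regime), disturbed = TRUE)
    run_scenario(sc)
  })
  if (disturbed) return(full)
  fixture(paste0("exp1_", regime), function() {
    tr <- full[full$time <= 64, ]
    attributes(tr) <- c(attributes(tr),
                        attributes(full)[c("config", "params", "schedule")])
    class(tr) <- class(full)
    tr
  })
}

## literature-kinetics continuous run for the washout comparison
exp1_literature_run <- function() {
  fixture("exp1_conti_lit", function() {
    sc <- preset_scenario("exp1_conti", preset = "literature")
    run_scenario(sc)
  })
}

## small deterministic profile set for metrics property tests
random_profiles <- function(n = 25, seed = 42) {
  fixture(paste0("profiles_", n, "_", seed), function() {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      k <- sample(2:40, 1)
      p <- stats::rgamma(k, sample(c(0.3, 1, 3), 1))
      p / sum(p)
    })
  })
}
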