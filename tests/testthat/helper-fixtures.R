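# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small landscape for generic pipeline tests
test_landscape <- function() {
  fixture("landscape_small", function() make_landscape(seed = 42,
                                                       extent_m = 3000))
}

test_cov_index <- function() {
  fixture("cov_index_small", function() covariate_index(test_landscape()))
}

# a single straight horizontal line at y = 0 from x = 0 to x = len,
# segmented and given constant attributes — handy for geometry oracles
toy_segments <- function(len = 1000, veght = 0.5, ewam = 0.2,
                         landcover = "Con", density = 1) {
  e <- segment_lines(list(cbind(c(0, len), c(0, 0))))
  e$veght <- veght; e$ewam <- ewam; e$landcover <- landcover
  e$density <- density
  e
}

# deterministic synthetic fix table: a constant-velocity track
toy_track <- function(n = 10, dt_h = 2, speed = 500, heading = 0,
                      start = c(0, 0), animal_id = "T1", species = "wolf",
                      t0 = as.POSIXct("2006-07-02 00:00:00", tz = "UTC")) {
  s <- speed * dt_h * (seq_len(n) - 1)
  data.frame(animal_id = animal_id, species = species, sex = "F",
             group = "P1", t = t0 + 3600 * dt_h * (seq_len(n) - 1),
             x = start[1] + s * cos(heading),
             y = start[2] + s * sin(heading), pfix = 1, weight = 1)
}

# the parameter-recovery cohort used by the acceptance checks: 20 animals x
# 300 steps on a seeded landscape, with strata and per-animal fits
recovery_cohort <- function() {
  fixture("recovery_cohort", function() {
    L <- make_landscape(seed = 101, extent_m = 5000)
    ci <- covariate_index(L)
    truth <- simulation_truth(beta = c(eDist = -1, "eDist:Veght" = 0.5),
                              seed = 7)
    sim_once <- function(rep_seed) {
      fixes <- do.call(rbind, lapply(1:20, function(i)
        simulate_ssf_track(L, truth, n_steps = 300,
                           seed = rep_seed * 1000 + i,
                           animal_id = sprintf("A%02d", i),
                           cov_index = ci)))
      st <- do.call(rbind, lapply(split(fixes, fixes$animal_id),
                                  function(tr) {
        s <- build_steps(tr)
        s$cluster <- paste0(s$animal_id[1], "_",
                            assign_clusters(s$t_start, 120))
        s
      }))
      rownames(st) <- NULL
      st
    }
    st <- sim_once(1)
    strata <- build_strata(st, L$segments, K = 10, seed = 1,
                           extent = L$extent, cov_index = ci)
    list(landscape = L, cov_index = ci, truth = truth,
         sim_once = sim_once, steps = st, strata = strata)
  })
}

# pooled estimate of the recovery model on one replicate cohort
recovery_pooled <- function(strata) {
  ind <- lapply(split(strata, strata$animal_id), function(d)
    suppressWarnings(fit_clogit(used ~ eDist * Veght, d,
                                strata = "stratum", cluster = "cluster")))
  population_average(ind)$table
}
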