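#' Generate the synthetic test-fixture bundle
#'
#' Writes, deterministically from `seed`: (i) synthetic current-clamp sweep
#' sets simulated from known parameters — one noiseless eLIF set (known
#' `tau_m`, `gL`, `E0 = Eu`), one mAdExp set with `a > 0` (known
#' `gL + a`), and a noisy copy with 0.5 mV Gaussian noise — for the
#' fitting estimators; (ii) canned spike-train files with known statistics
#' (a periodic train, CV = 0; independent Poisson trains; a duplicated
#' pair, CC = 1); and (iii) copies of all shipped preset configurations.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param sweep_currents step currents (pA) for the synthetic sweeps.
#' @param noise_sd Gaussian voltage noise of the noisy sweep copy (mV).
#' @return named list of written file paths, plus the true generating
#'   parameters under `$truth`.
#' @export
make_fixtures <- function(dir = tempfile("fixtures"), seed = 1,
                          sweep_currents = c(-60, -30, 10, 20, 30),
                          noise_sd = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  paths <- list()

  # --- fitting sweeps: slow energy dynamics so the RC response dominates
  gen_sweeps <- function(p) {
    sw <- lapply(sweep_currents, function(I) {
      proto <- step_protocol(I, onset = 200, offset = 900, duration = 1100)
      r <- simulate_neuron(p, proto, dt = 0.05, record_dt = 0.5)
      data.frame(t = r$times, V = r$V,
                 I = protocol_current(proto, r$times))
    })
    sweep_set(sw)
  }
  p_elif <- elif_params(Cm = 200, gL = 10, E0 = -65, Eu = -65, Ef = -60,
                        Ed = -20, epsc = 0, delta = 0, tau_e = 1e7,
                        Vth = -40)
  p_madexp <- madexp_params(Cm = 200, gL = 10, a = 2, E0 = -65, Eu = -65,
                            Ef = -60, Ed = -20, epsc = 0, delta = 0,
                            tau_e = 1e7, tau_w = 30, Vth = -40, Vpeak = 0,
                            DeltaT = 0.5, gamma = 1e7)
  ss_elif <- gen_sweeps(p_elif)
  ss_madexp <- gen_sweeps(p_madexp)
  noisy <- ss_elif
  noisy$sweeps <- lapply(noisy$sweeps, function(s) {
    s$V <- s$V + stats::rnorm(nrow(s), 0, noise_sd)
    s
  })
  paths$sweeps_elif <- write_sweeps(ss_elif,
                                    file.path(dir, "sweeps_elif.tsv"),
                                    c(kind = "noiseless eLIF"))
  paths$sweeps_madexp <- write_sweeps(ss_madexp,
                                      file.path(dir, "sweeps_madexp.tsv"),
                                      c(kind = "noiseless mAdExp"))
  paths$sweeps_noisy <- write_sweeps(noisy,
                                     file.path(dir, "sweeps_noisy.tsv"),
                                     c(kind = "0.5 mV noise"))

  # --- canned spike trains with known statistics
  periodic <- seq(100, 100e3, by = 100)            # 10 Hz, CV 0
  poisson5 <- sort(stats::runif(round(5 * 100), 0, 100e3))  # ~5 Hz, 100 s
  pois_list <- lapply(1:10, function(i)
    sort(stats::runif(stats::rpois(1, 5 * 100), 0, 100e3)))
  paths$train_periodic <- write_spike_trains(list(periodic),
                                             file.path(dir,
                                                       "train_periodic.tsv"))
  paths$train_poisson <- write_spike_trains(pois_list,
                                            file.path(dir,
                                                      "train_poisson.tsv"))
  paths$train_duplicated <- write_spike_trains(
    list(poisson5, poisson5), file.path(dir, "train_duplicated.tsv"))

  # --- preset copies
  preset_dir <- file.path(dir, "presets")
  dir.create(preset_dir, showWarnings = FALSE)
  for (nm in preset_names())
    file.copy(system.file("extdata", "presets", paste0(nm, ".yaml"),
                          package = "metaneuron"),
              file.path(preset_dir, paste0(nm, ".yaml")), overwrite = TRUE)
  paths$presets <- preset_dir
  paths$truth <- list(elif = p_elif, madexp = p_madexp,
                      poisson_rate = 5, periodic_rate = 10)
  paths
}
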