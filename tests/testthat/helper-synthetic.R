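# shared fixtures built in code

# a small noiseless synthetic study written to a temp dir; returns paths,
# the truth object and a matching run_config
make_noiseless_study <- function(n = 600, seed = 11, dir = NULL, ...) {
  if (is.null(dir)) dir <- tempfile("sim")
  cfg <- generator_config(n_residences = n, residual_sd = 0,
                          measurement_gsd = 1, outlier_fraction = 0,
                          seed = seed, ...)
  paths <- simulate_to_dir(cfg, dir)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  list(cfg = cfg, paths = paths, truth = truth,
       run_cfg = run_config_from_truth(paths, truth))
}

# run_config whose tunables mirror what the generator recorded in truth.json
run_config_from_truth <- function(paths, truth, ...) {
  run_config(residences = paths[["residences"]],
             districts = paths[["districts"]],
             meteo = paths[["meteo"]],
             survey = paths[["survey"]],
             seasonal_factors = unlist(truth$seasonal_factors),
             habit_weights = unlist(truth$habit_weights),
             ft = truth$ft, fw = truth$fw, Ti = truth$Ti, lam = truth$lam,
             soil_reference = truth$soil_reference,
             outdoor_reference = truth$outdoor_reference, ...)
}

truth_table <- function(truth) as.data.frame(truth$residences)

quiet_pipeline <- function(cfg) suppressMessages(run_pipeline(cfg))

# random but physically sensible mass-balance parameter draws
random_mb_params <- function() {
  mass_balance_params(
    Es = runif(1, 1, 50), Ebm = runif(1, 0, 5),
    kd_s = runif(1, 0.01, 0.5), kd_bm = runif(1, 0.01, 0.2),
    ka = runif(1, 0, 0.05), dP_si = runif(1, 0, 5),
    Sg = runif(1, 40, 150), Sbm = runif(1, 50, 400),
    V = runif(1, 100, 500), Co = runif(1, 0, 20)
  )
}
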