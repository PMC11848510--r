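#' Simulation experiment configuration
#'
#' Bundles everything [run_experiment()] needs to replicate the simulation
#' study: per-iteration parameter sampling ranges (baseline:
#' `rho ~ U(-3, -1)`, `alpha0 ~ U(-1, 0)`, `beta ~ U(-2, 2)` with `g0 = -3`,
#' `beta0 = 1`; sparse: fixed `rho = -2`, `alpha0 = -0.5`, `beta = 2`,
#' `g0 = -5` with the low-permeability detectors removed), the landscape
#' generator settings, the movement-simulation length, the estimator list
#' and the master seed. Two presets ship: `"paper"` is the full design
#' (50 x 50 grid, `t = 5000`, 100 iterations -- an overnight single-CPU
#' run) and `"desk"` a scaled-down version (30 x 30, `t = 2000`,
#' 10 iterations) for interactive work.
#'
#' @param preset `"paper"`, `"desk"`, or `"custom"` (then supply the sizes).
#' @param scenario_type `"baseline"` or `"sparse"`.
#' @param estimators subset of `c("adcr", "scr_lcp", "scr")`.
#' @param master_seed integer; per-iteration seeds are derived from it by a
#'   fixed affine congruential scheme, so any subset of iterations reruns
#'   identically.
#' @param out_dir optional checkpoint directory: each finished iteration is
#'   written as JSON and reloaded instead of recomputed on rerun.
#' @param n_iterations,nx,ny,n_patches,area_range,n_steps,burn_in size and
#'   length overrides for the preset.
#' @param det_spacing,det_margin detector-array layout (cells).
#' @param center_stride,lcp_exponent,hessian estimation settings.
#' @return an object of class `adcr_experiment_config`.
#' @export
experiment_config <- function(preset = c("desk", "paper", "custom"),
                              scenario_type = c("baseline", "sparse"),
                              estimators = c("adcr", "scr_lcp", "scr"),
                              master_seed = 1, out_dir = NULL,
                              n_iterations = NULL, nx = NULL, ny = NULL,
                              n_patches = 5, area_range = NULL,
                              n_steps = NULL, burn_in = 100,
                              det_spacing = 4, det_margin = NULL,
                              center_stride = 1, lcp_exponent = 1,
                              hessian = TRUE) {
  preset <- match.arg(preset)
  scenario_type <- match.arg(scenario_type)
  estimators <- match.arg(estimators, c("adcr", "scr_lcp", "scr"),
                          several.ok = TRUE)
  base <- switch(preset,
    paper = list(n_iterations = 100, nx = 50, ny = 50,
                 area_range = c(100, 250), n_steps = 5000, det_margin = 9),
    desk = list(n_iterations = 10, nx = 30, ny = 30,
                area_range = c(36, 90), n_steps = 2000, det_margin = 5),
    custom = list(n_iterations = 10, nx = 30, ny = 30,
                  area_range = c(36, 90), n_steps = 2000, det_margin = 5))
  cfg <- list(
    preset = preset, scenario_type = scenario_type, estimators = estimators,
    master_seed = as.integer(master_seed), out_dir = out_dir,
    n_iterations = n_iterations %||% base$n_iterations,
    nx = nx %||% base$nx, ny = ny %||% base$ny,
    n_patches = n_patches, area_range = area_range %||% base$area_range,
    n_steps = n_steps %||% base$n_steps, burn_in = burn_in,
    det_spacing = det_spacing, det_margin = det_margin %||% base$det_margin,
    center_stride = center_stride, lcp_exponent = lcp_exponent,
    hessian = hessian
  )
  stopifnot(cfg$n_iterations >= 1)
  structure(cfg, class = "adcr_experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-iteration seed derivation
#'
#' Deterministic, documented scheme: `(master * 48271 + i * 16807) mod
#' (2^31 - 1)`, kept within the positive 32-bit integer range.
#'
#' @param master_seed master seed.
#' @param i iteration index.
#' @return integer seed.
#' @export
iteration_seed <- function(master_seed, i) {
  s <- (as.numeric(master_seed) %% 2147483647) * 48271 + i * 16807
  as.integer(s %% 2147483647) + 1L
}

## draw true parameters for one iteration
draw_truth_ <- function(cfg) {
  if (cfg$scenario_type == "baseline") {
    list(rho = stats::runif(1, -3, -1), alpha0 = stats::runif(1, -1, 0),
         beta = stats::runif(1, -2, 2), g0 = -3, beta0 = 1)
  } else {
    list(rho = -2, alpha0 = -0.5, beta = 2, g0 = -5, beta0 = 1)
  }
}

## fit one estimator; returns list(fit or NULL, elapsed)
fit_estimator_ <- function(est, data, land, cfg) {
  t0 <- proc.time()[3]
  fit <- tryCatch(switch(est,
    adcr = fit_adcr(data, land, center_stride = cfg$center_stride,
                    hessian = cfg$hessian),
    scr = fit_scr(data, land, mode = "euclidean",
                  center_stride = cfg$center_stride, hessian = cfg$hessian),
    scr_lcp = fit_scr(data, land, mode = "lcp",
                      lcp_exponent = cfg$lcp_exponent,
                      center_stride = cfg$center_stride,
                      hessian = cfg$hessian)),
    error = function(e) e)
  list(fit = if (inherits(fit, "error")) NULL else fit,
       error = if (inherits(fit, "error")) conditionMessage(fit) else NA,
       elapsed = proc.time()[3] - t0)
}

## true/estimate bookkeeping for one fitted model
param_rows_ <- function(it, est, fit, truth) {
  ci <- fit$ci
  true_of <- function(term) {
    switch(term,
      rho = truth$rho,
      g0 = if (est == "adcr") truth$g0 else NA_real_,
      gamma0 = truth$beta0 - truth$alpha0,
      beta = truth$beta,
      NA_real_)
  }
  tibble::tibble(
    iteration = it, estimator = est, term = ci$term,
    true = unname(vapply(ci$term, true_of, numeric(1))),
    est = ci$estimate, se = ci$std.error,
    lo = ci$conf.low, hi = ci$conf.high,
    converged = fit$convergence
  )
}

run_iteration_ <- function(cfg, it) {
  withr::local_seed(iteration_seed(cfg$master_seed, it))
  truth <- draw_truth_(cfg)
  scn <- sim_scenario(
    rho = truth$rho, alpha0 = truth$alpha0, beta0 = truth$beta0,
    beta = truth$beta, g0 = truth$g0,
    n_steps = cfg$n_steps, burn_in = cfg$burn_in,
    patch_spec = list(nx = cfg$nx, ny = cfg$ny, n_patches = cfg$n_patches,
                      area_range = cfg$area_range),
    detector_spec = list(spacing = cfg$det_spacing,
                         margin = cfg$det_margin, K = 1),
    drop_low_permeability_detectors = cfg$scenario_type == "sparse")
  if (cfg$scenario_type == "sparse") scn$g0 <- -5
  sim <- simulate_dataset(scn)
  land <- sim$truth$land
  det <- sim$truth$detectors
  full_array <- baseline_detectors(land, spacing = cfg$det_spacing,
                                   margin = cfg$det_margin)
  region <- c(range(full_array$points$x), range(full_array$points$y))
  cc <- cell_centers(land)
  inside <- cc$x >= region[1] & cc$x <= region[2] &
    cc$y >= region[3] & cc$y <= region[4]
  true_hr <- homerange_params(truth$beta0 - truth$alpha0, truth$beta)
  P_true <- homerange_surface_batch_(true_hr, land, cc$x[inside],
                                     cc$y[inside])
  hda_true <- apply(P_true, 2, hda90, h = land$h)
  params <- list(); iters <- list()
  for (est in cfg$estimators) {
    if (sim$data$n == 0) {
      iters[[est]] <- tibble::tibble(
        iteration = it, estimator = est, failed = TRUE,
        error = "no individuals detected", converged = FALSE,
        overlap_mean = NA_real_, hda_mean_true = NA_real_,
        hda_mean_est = NA_real_, hda_sd_true = NA_real_,
        hda_sd_est = NA_real_, elapsed = 0)
      next
    }
    res <- fit_estimator_(est, sim$data, land, cfg)
    if (is.null(res$fit)) {
      iters[[est]] <- tibble::tibble(
        iteration = it, estimator = est, failed = TRUE, error = res$error,
        converged = FALSE, overlap_mean = NA_real_,
        hda_mean_true = NA_real_, hda_mean_est = NA_real_,
        hda_sd_true = NA_real_, hda_sd_est = NA_real_,
        elapsed = res$elapsed)
      next
    }
    Q_est <- homerange_surface_batch_(res$fit, land, cc$x[inside],
                                      cc$y[inside])
    hda_est <- apply(Q_est, 2, hda90, h = land$h)
    params[[est]] <- param_rows_(it, est, res$fit, truth)
    iters[[est]] <- tibble::tibble(
      iteration = it, estimator = est, failed = FALSE, error = NA_character_,
      converged = res$fit$convergence,
      overlap_mean = mean(colSums(pmin(P_true, Q_est))),
      hda_mean_true = mean(hda_true), hda_mean_est = mean(hda_est),
      hda_sd_true = stats::sd(hda_true), hda_sd_est = stats::sd(hda_est),
      elapsed = res$elapsed)
  }
  iters <- dplyr::bind_rows(iters)
  iters$N <- sim$truth$N
  iters$n_detected <- sim$data$n
  iters$n_detections <- sum(sim$data$Y)
  iters$detection_rate <- if (sim$truth$N > 0) sim$data$n / sim$truth$N
                          else NA_real_
  iters$beta_true <- truth$beta
  list(params = dplyr::bind_rows(params), iterations = iters)
}

#' Run a simulation experiment
#'
#' For each iteration: derive the iteration seed, draw true parameters and a
#' fresh patch landscape, simulate the movement-based capture--recapture
#' dataset, fit every requested estimator, and score home-range overlap and
#' 90% highest-density areas over the detector-array window. A failed fit
#' marks that iteration/estimator record as failed and the run continues.
#' With `out_dir` set, each iteration is checkpointed as JSON and reruns
#' resume from the checkpoints (byte-identical results given the master
#' seed).
#'
#' @param cfg an [experiment_config()].
#' @param quiet suppress per-iteration progress messages.
#' @return an object of class `adcr_experiment`: list with `params`
#'   (long tibble: iteration, estimator, term, true, est, se, lo, hi),
#'   `iterations` (per iteration x estimator summaries) and `config`.
#' @seealso [summarize_report()]
#' @export
run_experiment <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "adcr_experiment_config"))
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  out <- vector("list", cfg$n_iterations)
  for (it in seq_len(cfg$n_iterations)) {
    ckpt <- if (!is.null(cfg$out_dir)) {
      file.path(cfg$out_dir, sprintf("iteration_%04d.json", it))
    }
    if (!is.null(ckpt) && file.exists(ckpt)) {
      out[[it]] <- read_iteration_json_(ckpt)
      if (!quiet) message(sprintf("iteration %d: loaded checkpoint", it))
      next
    }
    t0 <- proc.time()[3]
    out[[it]] <- run_iteration_(cfg, it)
    if (!is.null(ckpt)) write_iteration_json_(out[[it]], ckpt)
    if (!quiet) {
      message(sprintf("iteration %d/%d done in %.1f s", it,
                      cfg$n_iterations, proc.time()[3] - t0))
    }
  }
  structure(list(params = dplyr::bind_rows(lapply(out, `[[`, "params")),
                 iterations = dplyr::bind_rows(lapply(out, `[[`,
                                                      "iterations")),
                 config = cfg),
            class = "adcr_experiment")
}

write_iteration_json_ <- function(rec, path) {
  jsonlite::write_json(rec, path, dataframe = "columns", digits = NA,
                       na = "null", auto_unbox = TRUE)
}

read_iteration_json_ <- function(path) {
  raw <- jsonlite::fromJSON(path)
  fix <- function(df, chr = character(0), lgl = character(0)) {
    df <- tibble::as_tibble(lapply(df, unlist))
    for (cn in names(df)) {
      if (cn %in% chr) df[[cn]] <- as.character(df[[cn]])
      else if (cn %in% lgl) df[[cn]] <- as.logical(df[[cn]])
    }
    df
  }
  params <- if (length(raw$params)) {
    fix(raw$params, chr = c("estimator", "term"), lgl = "converged")
  } else tibble::tibble()
  iterations <- fix(raw$iterations, chr = c("estimator", "error"),
                    lgl = c("failed", "converged"))
  list(params = params, iterations = iterations)
}

#' Summary report of a simulation experiment
#'
#' Aggregates experiment records into the study's headline quantities:
#' the RMSE/MBE table of log density binned by the true landscape effect
#' (`beta < -0.5`, `|beta| <= 0.5`, `beta > 0.5`, plus the total), RMSE/MBE
#' of ADCR's `g0`, Pearson correlations of true versus estimated `beta` and
#' `gamma0` (and of true `beta` versus the LCP cost coefficient `g2`, whose
#' expected relationship is negative), mean and variance of home-range
#' overlap per estimator, mean bias of the mean and SD of home-range size,
#' CI-exclusion and sign-error counts for the landscape effect, and failure
#' counts. Estimators with no successful records are omitted with a
#' warning.
#'
#' @param x an `adcr_experiment` from [run_experiment()] (or a list with
#'   `params` and `iterations` tibbles).
#' @return an object of class `adcr_report`: a named list of tibbles
#'   (`density`, `g0`, `correlations`, `overlap`, `hda`, `landscape_effect`,
#'   `failures`).
#' @export
summarize_report <- function(x) {
  params <- x$params; iters <- x$iterations
  stopifnot(is.data.frame(iters))
  present <- unique(iters$estimator[!iters$failed])
  missing <- setdiff(unique(iters$estimator), present)
  if (length(missing)) {
    warning("no successful iterations for: ", paste(missing, collapse = ", "),
            "; omitted from the report")
  }
  bin_of <- function(beta) {
    dplyr::case_when(beta < -0.5 ~ "beta < -0.5",
                     beta > 0.5 ~ "beta > 0.5",
                     TRUE ~ "|beta| <= 0.5")
  }
  rho <- dplyr::filter(params, .data$term == "rho",
                       .data$estimator %in% present)
  rho$bin <- bin_of(iters$beta_true[match(paste(rho$iteration,
                                                rho$estimator),
                                          paste(iters$iteration,
                                                iters$estimator))])
  density <- dplyr::bind_rows(
    dplyr::summarise(dplyr::group_by(rho, .data$estimator),
                     bin = "Total", accuracy_summary(dplyr::pick(
                       dplyr::everything())), .groups = "drop"),
    dplyr::summarise(dplyr::group_by(rho, .data$estimator, .data$bin),
                     accuracy_summary(dplyr::pick(dplyr::everything())),
                     .groups = "drop"))
  g0 <- dplyr::filter(params, .data$term == "g0", .data$estimator == "adcr",
                      is.finite(.data$true))
  g0_tab <- if (nrow(g0)) accuracy_summary(g0) else tibble::tibble()
  corr <- dplyr::bind_rows(
    dplyr::mutate(accuracy_summary(
      dplyr::filter(params, .data$term == "beta",
                    .data$estimator == "adcr")),
      estimator = "adcr", quantity = "beta"),
    dplyr::mutate(accuracy_summary(
      dplyr::filter(params, .data$term == "gamma0",
                    .data$estimator == "adcr")),
      estimator = "adcr", quantity = "gamma0"))
  g2 <- dplyr::filter(params, .data$term == "g2",
                      .data$estimator == "scr_lcp")
  if (nrow(g2)) {
    bt <- iters$beta_true[match(paste(g2$iteration, g2$estimator),
                                paste(iters$iteration, iters$estimator))]
    r <- if (length(bt) >= 2 && stats::sd(bt) > 0) stats::cor(bt, g2$est)
         else NA_real_
    corr <- dplyr::bind_rows(corr, tibble::tibble(
      n = nrow(g2), rmse = NA, mbe = NA, pearson_r = r,
      ci_exclusion_count = sum(g2$lo > 0 | g2$hi < 0, na.rm = TRUE),
      estimator = "scr_lcp", quantity = "g2 vs true beta"))
  }
  ok <- dplyr::filter(iters, !.data$failed,
                      .data$estimator %in% present)
  overlap <- dplyr::summarise(
    dplyr::group_by(ok, .data$estimator),
    n = dplyr::n(), mean = mean(.data$overlap_mean),
    variance = stats::var(.data$overlap_mean), .groups = "drop")
  hda <- dplyr::summarise(
    dplyr::group_by(ok, .data$estimator),
    mbe_mean_hda = mean(.data$hda_mean_est - .data$hda_mean_true),
    mbe_sd_hda = mean(.data$hda_sd_est - .data$hda_sd_true),
    .groups = "drop")
  eff <- dplyr::bind_rows(
    dplyr::filter(params, .data$term == "beta", .data$estimator == "adcr"),
    g2)
  landscape_effect <- if (nrow(eff)) {
    bt <- iters$beta_true[match(paste(eff$iteration, eff$estimator),
                                paste(iters$iteration, iters$estimator))]
    eff$expected_sign <- ifelse(eff$term == "beta", sign(bt), -sign(bt))
    dplyr::summarise(
      dplyr::group_by(eff, .data$estimator),
      n = dplyr::n(),
      ci_excludes_zero = sum(.data$lo > 0 | .data$hi < 0, na.rm = TRUE),
      sign_errors = sum(sign(.data$est) != .data$expected_sign &
                          .data$expected_sign != 0),
      .groups = "drop")
  } else tibble::tibble()
  failures <- dplyr::summarise(
    dplyr::group_by(iters, .data$estimator),
    n = dplyr::n(), failed = sum(.data$failed),
    not_converged = sum(!.data$converged & !.data$failed),
    .groups = "drop")
  structure(list(density = density, g0 = g0_tab, correlations = corr,
                 overlap = overlap, hda = hda,
                 landscape_effect = landscape_effect, failures = failures),
            class = "adcr_report")
}

#' @export
print.adcr_report <- function(x, ...) {
  cat("== Log-density accuracy (RMSE / MBE) ==\n")
  print(as.data.frame(x$density), row.names = FALSE, digits = 4)
  if (nrow(x$g0)) {
    cat("\n== ADCR g0 accuracy ==\n")
    print(as.data.frame(x$g0), row.names = FALSE, digits = 4)
  }
  cat("\n== True-vs-estimated correlations ==\n")
  print(as.data.frame(x$correlations), row.names = FALSE, digits = 4)
  cat("\n== Home-range overlap ==\n")
  print(as.data.frame(x$overlap), row.names = FALSE, digits = 4)
  cat("\n== Home-range size (90% HDA) bias ==\n")
  print(as.data.frame(x$hda), row.names = FALSE, digits = 4)
  if (nrow(x$landscape_effect)) {
    cat("\n== Landscape effect: CI exclusion of zero / sign errors ==\n")
    print(as.data.frame(x$landscape_effect), row.names = FALSE, digits = 4)
  }
  cat("\n== Failures ==\n")
  print(as.data.frame(x$failures), row.names = FALSE, digits = 4)
  invisible(x)
}
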