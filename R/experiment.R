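# Experiment runner: comparison protocol (methods x masks x rates x repeats,
# metrics averaged over repeats), per-iteration convergence curves, and
# one-at-a-time parameter sweeps.

#' Define an experiment plan
#'
#' @param methods subset of `"zero_fill"`, `"dip"`, `"rws_dip"`.
#' @param mask_schemes subset of `"cartesian"`, `"radial"`,
#'   `"variable_density"`.
#' @param rates sampling rates in (0, 1].
#' @param repeats phantom pairs (and reconstruction repeats) per cell.
#' @param scale `"full"` (full-scale published settings, 256 x 256) or
#'   `"desk"` (CPU-sized: 128 x 128, depth-4 network, 10 x 50 iterations).
#' @param base_seed first seed of the phantom/mask/training family.
#' @param output_dir where CSV/JSON outputs are written; `NULL` disables file
#'   output.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(methods = c("zero_fill", "dip", "rws_dip"),
                            mask_schemes = "cartesian",
                            rates = 0.3, repeats = 3L,
                            scale = c("desk", "full"),
                            base_seed = 1L, output_dir = NULL) {
  scale <- match.arg(scale)
  known_m <- c("zero_fill", "dip", "rws_dip")
  known_s <- c("cartesian", "radial", "variable_density")
  if (!all(methods %in% known_m))
    stop("unknown method(s): ", paste(setdiff(methods, known_m), collapse = ", "),
         call. = FALSE)
  if (!all(mask_schemes %in% known_s))
    stop("unknown mask scheme(s): ",
         paste(setdiff(mask_schemes, known_s), collapse = ", "), call. = FALSE)
  stopifnot(repeats >= 1, all(rates > 0 & rates <= 1))
  structure(list(methods = methods, mask_schemes = mask_schemes, rates = rates,
                 repeats = as.integer(repeats), scale = scale,
                 base_seed = as.integer(base_seed), output_dir = output_dir),
            class = "experiment_plan")
}

plan_image_side <- function(plan) if (plan$scale == "desk") 128L else 256L

plan_config <- function(plan, seed, overrides = list()) {
  cfg <- if (plan$scale == "desk") desk_admm_config(seed = seed)
         else admm_config(seed = seed)
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop("unknown config override `", nm, "`",
                                  call. = FALSE)
    cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

make_mask <- function(scheme, n, rate, seed) {
  switch(scheme,
         cartesian = make_cartesian_mask(n, rate, seed),
         radial = make_radial_mask(n, rate),
         variable_density = make_variable_density_mask(n, rate, seed))
}

run_one <- function(method, y, pair, cfg) {
  if (method == "zero_fill") {
    img <- zero_fill(y)
    list(recon = img, history = NULL)
  } else if (method == "dip") {
    rep <- dip_reconstruct(y, cfg, truth = pair$target)
    list(recon = rep$recon_final, history = rep$history)
  } else {
    rep <- rws_dip_reconstruct(y, pair$reference, cfg, truth = pair$target)
    list(recon = rep$recon_final, history = rep$history)
  }
}

#' Run a comparative reconstruction experiment
#'
#' For every (method, scheme, rate, repeat) cell: generate the phantom pair,
#' simulate the acquisition, reconstruct and score against the target. Metrics
#' are averaged over repeats in the returned summary (RelErr reported as a
#' percentage). When `plan$output_dir` is set, per-run JSON metrics, the
#' aggregated summary CSV and per-iteration convergence CSVs are written
#' there; outputs carry the `scale` label so scaled-down runs are never
#' mistaken for full-scale ones.
#'
#' @param plan an [experiment_plan()].
#' @param cfg_overrides named list of [admm_config()] fields to override
#'   (e.g. `list(rho = 0.1)`).
#' @return Invisible list with `runs` (one row per run) and `summary` (one row
#'   per cell with mean metrics); the summary is also returned as the
#'   `summary` element.
#' @export
run_experiment <- function(plan, cfg_overrides = list()) {
  stopifnot(inherits(plan, "experiment_plan"))
  n <- plan_image_side(plan)
  out_dir <- plan$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  rows <- list()
  for (scheme in plan$mask_schemes) for (rate in plan$rates)
    for (r in seq_len(plan$repeats)) {
      seed <- plan$base_seed + r - 1L
      pair <- generate_pair(phantom_pair_config(n = n, seed = seed))
      mask <- make_mask(scheme, n, rate, seed)
      y <- undersample(pair$target, mask)
      for (method in plan$methods) {
        cfg <- plan_config(plan, seed, cfg_overrides)
        res <- run_one(method, y, pair, cfg)
        m <- metric_report(res$recon, pair$target)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, scheme = scheme, rate = rate, repeat_ = r,
          seed = seed, scale = plan$scale, relerr_pct = 100 * m$relerr,
          psnr_db = m$psnr, ssim = m$ssim)
        if (!is.null(out_dir)) {
          tag <- sprintf("%s_%s_%03d_r%d", method, scheme,
                         round(1000 * rate), r)
          jsonlite::write_json(
            list(method = method, scheme = scheme, rate = rate, repeat_ = r,
                 seed = seed, scale = plan$scale,
                 relerr_pct = 100 * m$relerr, psnr_db = m$psnr,
                 ssim = m$ssim),
            file.path(out_dir, paste0("run_", tag, ".json")),
            auto_unbox = TRUE, digits = NA)
          if (!is.null(res$history))
            utils::write.csv(res$history,
                             file.path(out_dir, paste0("history_", tag, ".csv")),
                             row.names = FALSE)
        }
      }
    }
  runs <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(relerr_pct, psnr_db, ssim) ~ method + scheme + rate, data = runs,
    FUN = mean)
  summary$scale <- plan$scale
  summary <- summary[order(summary$scheme, summary$rate, summary$method), ]
  if (!is.null(out_dir))
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  invisible(list(runs = runs, summary = summary))
}

#' One-at-a-time parameter sweep
#'
#' Varies `rho` or `lam` over `values` while keeping everything else at the
#' plan's settings, running the reference-driven method only, and reports mean
#' PSNR (over repeats) per (value, rate).
#'
#' @param param `"rho"` or `"lam"`.
#' @param values numeric vector of parameter values.
#' @param plan an [experiment_plan()].
#' @param cfg_overrides further fixed [admm_config()] overrides applied to
#'   every point of the sweep.
#' @return Data frame with columns `param`, `value`, `scheme`, `rate`,
#'   `psnr_db` (one row per value x scheme x rate); written to
#'   `sweep_<param>.csv` when the plan has an output directory.
#' @export
sweep_parameters <- function(param = c("rho", "lam"), values, plan,
                             cfg_overrides = list()) {
  param <- match.arg(param)
  stopifnot(length(values) >= 1)
  rows <- list()
  for (v in values) {
    ov <- c(stats::setNames(list(v), param), cfg_overrides)
    sub <- plan
    sub$methods <- "rws_dip"
    sub$output_dir <- NULL
    res <- run_experiment(sub, cfg_overrides = ov)
    s <- res$summary
    rows[[length(rows) + 1L]] <- data.frame(
      param = param, value = v, scheme = s$scheme, rate = s$rate,
      psnr_db = s$psnr_db)
  }
  curve <- do.call(rbind, rows)
  if (!is.null(plan$output_dir)) {
    dir.create(plan$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(curve,
                     file.path(plan$output_dir,
                               paste0("sweep_", param, ".csv")),
                     row.names = FALSE)
  }
  curve
}
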