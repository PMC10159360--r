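#' Build a synthetic benchmark dataset
#'
#' Generates the default study conditions in one call: a chromatic binary
#' dense-noise stimulus, a simulated LN population responding to it, and the
#' three autoencoder corpora (structured 1/f images, their phase-scrambled
#' controls, and white noise).
#'
#' @param n_neurons number of simulated neurons (default 50).
#' @param n_frames stimulus length in frames, test sequence included
#'   (default 2450: 2400 train/validation + 50 test frames at 5 Hz).
#' @param n_images corpus size for the EC branch (default 400).
#' @param height,width frame size (default 28 x 28).
#' @param frame_rate stimulus rate in Hz (default 5).
#' @param n_test_repeats simulated test repeats (default 6).
#' @param rf_params overrides passed to [simulate_ln_population].
#' @param seed integer seed.
#' @return List with `data` (list of `stimulus`, `responses`), `neurons`
#'   (ground truth), and `corpora` (list `structured`, `phase_scrambled`,
#'   `white_noise`).
#' @export
make_benchmark <- function(n_neurons = 50, n_frames = 2450, n_images = 400,
                           height = 28, width = 28, frame_rate = 5,
                           n_test_repeats = 6, rf_params = list(), seed = 1) {
  stim <- generate_binary_noise(height, width, n_frames, 2, frame_rate,
                                seed = seed)
  sim <- simulate_ln_population(n_neurons, stim, rf_params = rf_params,
                                n_test_repeats = n_test_repeats,
                                seed = seed + 1)
  structured <- generate_structured_images(n_images, height, width,
                                           seed = seed + 2)
  scrambled <- phase_scramble(structured, seed = seed + 3)
  noise <- generate_white_noise_images(n_images, height, width,
                                       seed = seed + 4)
  list(data = list(stimulus = stim, responses = sim$responses),
       neurons = sim$neurons,
       corpora = list(structured = structured, phase_scrambled = scrambled,
                      white_noise = noise))
}

#' Run a model-comparison experiment
#'
#' Trains every requested model across seeds on one dataset, evaluates
#' per-neuron test correlations and the Gaussian-plausibility of the shared
#' filters, and collects pairwise permutation-test comparisons with bootstrap
#' confidence intervals. A failed training run is recorded per cell and does
#' not abort the remaining grid.
#'
#' @param data list with `stimulus` and `responses` (see [train_model]).
#' @param models named list; each element is a list with `config` (a
#'   [hybrid_config]) and optionally `ec_corpus`.
#' @param seeds integer vector of seeds.
#' @param compare optional list of 2-element character vectors naming model
#'   pairs to compare (default: every model against the first).
#' @param n_perm permutations for the pairwise tests.
#' @return An object of class `eval_report`: `cc` (data.frame model, seed,
#'   neuron, cc), `filter_r2` (data.frame model, seed, mean_r2), `summary`
#'   (per-model means and bootstrap CIs), `comparisons` (data.frame with
#'   p-values), `errors` (failed cells).
#' @export
run_experiment <- function(data, models, seeds = 1:3, compare = NULL,
                           n_perm = 10000) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  cc_rows <- list(); r2_rows <- list(); errors <- list()
  fits <- list()
  for (mn in names(models)) {
    for (s in seeds) {
      res <- tryCatch({
        m <- train_model(data, models[[mn]]$ec_corpus, models[[mn]]$config,
                         seed = s)
        ev <- evaluate_model(m, data)
        fr2 <- shared_filter_r2(m)
        list(model = m, cc = ev$cc, r2 = fr2$mean_r2)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(mn, s, sep = "/")]] <- conditionMessage(res)
        next
      }
      cc_rows[[paste(mn, s)]] <- data.frame(
        model = mn, seed = s, neuron = seq_along(res$cc), cc = res$cc)
      r2_rows[[paste(mn, s)]] <- data.frame(model = mn, seed = s,
                                            mean_r2 = res$r2)
      fits[[paste(mn, s, sep = "/")]] <- res$model
    }
  }
  cc <- do.call(rbind, cc_rows)
  r2 <- do.call(rbind, r2_rows)
  summary <- NULL; comparisons <- NULL
  if (!is.null(cc)) {
    per_model_neuron <- function(mn) {
      sub <- cc[cc$model == mn, ]
      # per-neuron CC averaged over seeds
      tapply(sub$cc, sub$neuron, mean, na.rm = TRUE)
    }
    mods <- unique(cc$model)
    summary <- do.call(rbind, lapply(mods, function(mn) {
      v <- per_model_neuron(mn)
      ci <- bootstrap_ci(v[is.finite(v)], seed = 1)
      data.frame(model = mn, mean_cc = mean(v, na.rm = TRUE),
                 cc_lo = ci[1], cc_hi = ci[2],
                 mean_r2 = mean(r2$mean_r2[r2$model == mn]))
    }))
    if (is.null(compare) && length(mods) > 1)
      compare <- lapply(mods[-1], function(mn) c(mods[1], mn))
    if (!is.null(compare)) {
      comparisons <- do.call(rbind, lapply(compare, function(pr) {
        a <- per_model_neuron(pr[1]); b <- per_model_neuron(pr[2])
        ok <- is.finite(a) & is.finite(b)
        data.frame(model_a = pr[1], model_b = pr[2],
                   delta = mean(b[ok] - a[ok]),
                   p_value = compare_models(a[ok], b[ok], n_perm = n_perm,
                                            seed = 1))
      }))
    }
  }
  structure(list(cc = cc, filter_r2 = r2, summary = summary,
                 comparisons = comparisons, errors = errors, models = fits),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  if (length(x$errors))
    cat(sprintf("failed cells: %s\n", paste(names(x$errors), collapse = ", ")))
  invisible(x)
}

#' Data-efficiency curve
#'
#' Re-trains the requested models at several training-data fractions
#' (leading contiguous segment; learning rate doubled below the full data
#' size) and tabulates test correlation and filter plausibility per fraction.
#'
#' @inheritParams run_experiment
#' @param fractions numeric vector in `(0, 1]`.
#' @return List with `table` (data.frame fraction, model, mean test CC, mean
#'   filter R2) and `reports` (one [run_experiment] report per fraction).
#' @export
data_efficiency_curve <- function(data, models, fractions, seeds = 1:3) {
  if (any(fractions <= 0 | fractions > 1))
    stop("`fractions` must lie in (0, 1]")
  reports <- list()
  rows <- list()
  for (f in fractions) {
    mods_f <- lapply(models, function(m) {
      m$config$data_fraction <- f
      m
    })
    rep_f <- run_experiment(data, mods_f, seeds = seeds)
    reports[[as.character(f)]] <- rep_f
    if (!is.null(rep_f$summary))
      rows[[as.character(f)]] <- cbind(fraction = f, rep_f$summary)
  }
  list(table = do.call(rbind, rows), reports = reports)
}

#' Persist an evaluation report as plain-text files
#'
#' Writes the per-neuron correlations, filter scores, summary and
#' comparisons as CSV, plus a JSON sidecar with the run metadata.
#'
#' @param report an [run_experiment] result.
#' @param dir output directory (created if missing).
#' @param meta optional list stored in the JSON sidecar.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, meta = list()) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$cc))
    utils::write.csv(report$cc, file.path(dir, "cc.csv"), row.names = FALSE)
  if (!is.null(report$filter_r2))
    utils::write.csv(report$filter_r2, file.path(dir, "filter_r2.csv"),
                     row.names = FALSE)
  if (!is.null(report$summary))
    utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                     row.names = FALSE)
  if (!is.null(report$comparisons))
    utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  meta$errors <- report$errors
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
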