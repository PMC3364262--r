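# Orchestration: extant-only analysis, full (extant + unknown/fossil)
# analysis with flight-mode prediction, and a thin command-line front end.

# standardize, resample and phi-transform a list of raw outline curves
.prepare_scores <- function(curves, n_points = 100L, use_correlation = TRUE,
                            extended = FALSE) {
  prepped <- lapply(curves, function(cv) {
    resample_equal_arclength(orient_standard(cv), n_points)
  })
  if (extended) {
    extended_eigenshape_fit(prepped, use_correlation = use_correlation)
  } else {
    eigenshape_fit(lapply(prepped, phi_transform),
                   use_correlation = use_correlation)
  }
}

#' Run the extant-only analysis
#'
#' End-to-end analysis of a labeled dataset: orientation, equal
#' arc-length resampling (default 100 pseudolandmarks), eigenshape
#' decomposition on the correlation matrix, phylogenetic signal tests per
#' retained axis, simulation-null phylogenetic MANOVA and per-axis ANOVAs
#' with phylogenetic Tukey HSD grids, and (when a mass column is present)
#' phylogenetic RMA of the first axis on log body mass.
#'
#' @param curves list of [outline_curve()] objects (profile view), one per
#'   specimen.
#' @param metadata data.frame with columns `specimen_id`, `flight_mode`
#'   and optionally `log_mass`; every specimen must be labeled.
#' @param tree a `phylo` covering the specimens.
#' @param n_points pseudolandmarks per curve.
#' @param retained_axes leading eigenshape axes carried into the tests.
#' @param n_perm permutations for the signal tests.
#' @param n_sim simulation replicates for the phylogenetic p-values.
#' @param seed RNG seed recorded in the bundle.
#' @param out_dir optional directory; when given, scores, variance table,
#'   signal table, test summaries and Tukey grids are written as CSV with
#'   a manifest.
#' @return a `report_bundle` list: `model`, `scores`, `signal`, `manova`,
#'   `anova` (per axis), `tukey` (per axis), `rma` (or `NULL`),
#'   `diagnostics`, `seed`.
#' @export
run_extant_analysis <- function(curves, metadata, tree, n_points = 100L,
                                retained_axes = 3L, n_perm = 199L,
                                n_sim = 199L, seed = 1L, out_dir = NULL) {
  ids <- vapply(curves, `[[`, character(1), "specimen_id")
  meta <- metadata[match(ids, metadata$specimen_id), ]
  if (anyNA(meta$flight_mode) ||
      any(meta$flight_mode %in% c("", "unknown"))) {
    stop("unlabeled specimen(s) in extant-only analysis: ",
         paste(ids[is.na(meta$flight_mode) |
                     meta$flight_mode %in% c("", "unknown")],
               collapse = ", "))
  }
  model <- .prepare_scores(curves, n_points)
  k <- min(retained_axes, ncol(model$scores))
  sc <- model$scores[, seq_len(k), drop = FALSE]
  groups <- stats::setNames(meta$flight_mode, meta$specimen_id)
  signal <- signal_table(sc, tree, n_perm = n_perm, seed = seed)
  manova <- phyl_anova(sc, groups, tree, n_sim = n_sim, seed = seed)
  anovas <- list()
  tukeys <- list()
  for (j in seq_len(k)) {
    x <- stats::setNames(sc[, j], rownames(sc))
    anovas[[colnames(sc)[j]]] <-
      phyl_anova(x, groups, tree, n_sim = n_sim, seed = seed + j)
    tukeys[[colnames(sc)[j]]] <-
      phyl_tukey_hsd(x, groups, tree, n_sim = n_sim, seed = seed + j)
  }
  rma <- NULL
  if ("log_mass" %in% names(metadata) && !anyNA(meta$log_mass)) {
    es1 <- stats::setNames(sc[, 1L], rownames(sc))
    mass <- stats::setNames(meta$log_mass, meta$specimen_id)
    rma <- phyl_rma(mass, es1, tree)
  }
  bundle <- list(model = model, scores = sc, signal = signal,
                 manova = manova, anova = anovas, tukey = tukeys,
                 rma = rma,
                 diagnostics = assumption_diagnostics(sc, groups[rownames(sc)]),
                 seed = seed)
  class(bundle) <- "report_bundle"
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

#' Run the full analysis with unknown taxa
#'
#' Refits the eigenshape decomposition on the combined sample (training +
#' unknown; a fresh decomposition rather than projection, so the shape
#' variance of the combined sample is maximized), optimizes Pagel's lambda
#' on the training tips, trains the phylogenetic discriminant, reports the
#' training resubstitution confusion matrix, predicts each unknown tip and
#' sweeps lambda to gauge prediction stability. Ternary coordinates of the
#' first three axes (min-max rescaled magnitudes normalized to sum 1) are
#' included for plotting.
#'
#' @inheritParams run_extant_analysis
#' @param metadata data.frame with `specimen_id` and `flight_mode`;
#'   unknowns flagged by `"unknown"` (or `NA`/empty).
#' @param sweep_grid lambda grid for the stability sweep.
#' @return a `report_bundle` list: `model`, `scores`, `lambda`,
#'   `pfda_model`, `confusion` (training resubstitution), `predictions`,
#'   `sweep`, `ternary`, `seed`.
#' @export
run_full_analysis <- function(curves, metadata, tree, n_points = 100L,
                              retained_axes = 3L, seed = 1L,
                              sweep_grid = seq(0, 1, by = 0.1),
                              out_dir = NULL) {
  ids <- vapply(curves, `[[`, character(1), "specimen_id")
  meta <- metadata[match(ids, metadata$specimen_id), ]
  lab <- meta$flight_mode
  unknown <- is.na(lab) | lab %in% c("", "unknown")
  if (!any(unknown)) stop("no unknown specimens flagged in metadata")
  missing_tip <- setdiff(ids, tree$tip.label)
  if (length(missing_tip)) {
    stop("specimen(s) absent from tree: ",
         paste(missing_tip, collapse = ", "))
  }
  model <- .prepare_scores(curves, n_points)
  k <- min(retained_axes, ncol(model$scores))
  sc <- model$scores[, seq_len(k), drop = FALSE]
  train_sc <- sc[!unknown, , drop = FALSE]
  unk_sc <- sc[unknown, , drop = FALSE]
  groups <- stats::setNames(lab[!unknown], ids[!unknown])
  opt <- optimize_lambda(train_sc, groups, tree)
  fit <- pfda_train(train_sc, groups, tree, opt$lambda_opt)
  resub <- pfda_predict(fit, train_sc, tree)
  confusion <- confusion_summary(as.character(groups[resub$tip]),
                                 resub$predicted)
  predictions <- pfda_predict(fit, unk_sc, tree)
  sweep_res <- lambda_sweep(train_sc, groups, unk_sc, tree, sweep_grid)
  ternary <- ternary_coordinates(sc)
  bundle <- list(model = model, scores = sc, lambda = opt,
                 pfda_model = fit, confusion = confusion,
                 predictions = predictions, sweep = sweep_res,
                 ternary = ternary, seed = seed)
  class(bundle) <- "report_bundle"
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

#' Ternary plotting coordinates for three eigenshape axes
#'
#' Rescales the absolute scores of the first three axes to [0, 1]
#' (min-max, per axis) and normalizes each specimen's triple to sum to 1,
#' giving barycentric coordinates for a ternary morphospace plot.
#'
#' @param scores specimens x >= 3 score matrix.
#' @return specimens x 3 matrix whose rows sum to 1.
#' @export
ternary_coordinates <- function(scores) {
  sc <- abs(as.matrix(scores)[, 1:3, drop = FALSE])
  rng <- apply(sc, 2L, range)
  sc <- sweep(sc, 2L, rng[1L, ])
  sc <- sweep(sc, 2L, pmax(rng[2L, ] - rng[1L, ], 1e-12), "/")
  tot <- rowSums(sc)
  tot[tot < 1e-12] <- 1
  sc / tot
}

.write_csv_12 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                scientific = TRUE,
                                                trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_csv_12(df, p)
    files <<- c(files, name)
  }
  put(data.frame(specimen_id = rownames(bundle$scores), bundle$scores,
                 check.names = FALSE), "scores.csv")
  put(data.frame(axis = colnames(bundle$model$axes),
                 variance_fraction = bundle$model$variance_fraction,
                 cumulative = cumsum(bundle$model$variance_fraction)),
      "variance.csv")
  if (!is.null(bundle$signal)) put(bundle$signal, "signal.csv")
  if (!is.null(bundle$tukey)) {
    for (nm in names(bundle$tukey)) {
      put(bundle$tukey[[nm]], paste0("tukey_", nm, ".csv"))
    }
  }
  if (!is.null(bundle$confusion)) {
    cm <- bundle$confusion
    df <- data.frame(predicted = rownames(cm$counts), cm$counts,
                     check.names = FALSE)
    df <- rbind(df, c("% Correct", paste0(cm$percent_correct, "%")))
    put(df, "confusion.csv")
  }
  if (!is.null(bundle$predictions)) put(bundle$predictions,
                                        "predictions.csv")
  if (!is.null(bundle$sweep)) {
    put(data.frame(tip = rownames(bundle$sweep$table), bundle$sweep$table,
                   stability = bundle$sweep$stability,
                   check.names = FALSE), "lambda_sweep.csv")
  }
  if (!is.null(bundle$lambda)) put(bundle$lambda$profile,
                                   "lambda_profile.csv")
  if (!is.null(bundle$ternary)) {
    put(data.frame(specimen_id = rownames(bundle$ternary), bundle$ternary,
                   check.names = FALSE), "ternary.csv")
  }
  writeLines(c(paste0("seed=", bundle$seed),
               paste0("created=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               files),
             file.path(out_dir, "MANIFEST.txt"))
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Thin front end over the package's functions, intended to be called from
#' an `Rscript` wrapper. Subcommands: `simulate` (write a synthetic
#' dataset), `extant` (extant-only analysis of a dataset directory),
#' `full` (analysis with unknown taxa and flight-mode prediction),
#' `sensitivity` (curve-definition ranking on a simulated dataset) and
#' `fixtures` (print a packaged fixture as CSV).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 success, 2 usage error), invisibly.
#' @export
furcula_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: furcula <simulate|extant|full|sensitivity|fixtures> [options]\n",
        "  simulate --seed N --out DIR [--n-per-class N]\n",
        "  extant   --data DIR --seed N [--out DIR]\n",
        "  full     --data DIR --seed N [--out DIR]\n",
        "  fixtures <table1_specimens|table2_mesozoic|table6_confusion>\n",
        sep = "")
  }
  if (!length(args)) { usage(); return(invisible(2L)) }
  if (args[1L] %in% c("--help", "-h")) { usage(); return(invisible(0L)) }
  if (args[1L] == "--version") {
    cat(as.character(utils::packageVersion("furculashape")), "\n")
    return(invisible(0L))
  }
  cmd <- args[1L]
  opts <- list()
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    if (startsWith(rest[i], "--")) {
      key <- sub("^--", "", rest[i])
      if (i + 1L > length(rest) || startsWith(rest[i + 1L], "--")) {
        cat("missing value for --", key, "\n", sep = ""); usage()
        return(invisible(2L))
      }
      opts[[key]] <- rest[i + 1L]
      i <- i + 2L
    } else {
      opts[["positional"]] <- c(opts[["positional"]], rest[i])
      i <- i + 1L
    }
  }
  res <- tryCatch({
    switch(cmd,
      simulate = {
        if (is.null(opts$seed)) stop("--seed is required", call. = FALSE)
        if (is.null(opts$out)) stop("--out is required", call. = FALSE)
        npc <- as.integer(opts[["n-per-class"]] %||% "10")
        ds <- simulate_dataset(
          stats::setNames(rep(npc, 5), c("CF", "FG", "IB", "S", "PF")),
          seed = as.integer(opts$seed))
        write_dataset(ds, opts$out,
                      config = list(seed = opts$seed, n_per_class = npc))
        0L
      },
      extant = , full = {
        if (is.null(opts$seed)) stop("--seed is required", call. = FALSE)
        if (is.null(opts$data)) stop("--data is required", call. = FALSE)
        curves <- read_outline_csv(file.path(opts$data,
                                             "outlines_profile.csv"))
        meta <- utils::read.csv(file.path(opts$data, "metadata.csv"),
                                stringsAsFactors = FALSE)
        tree <- parse_newick(paste(readLines(file.path(opts$data,
                                                       "tree.nwk")),
                                   collapse = ""))
        if (cmd == "extant") {
          run_extant_analysis(curves, meta, tree,
                              seed = as.integer(opts$seed),
                              out_dir = opts$out)
        } else {
          run_full_analysis(curves, meta, tree,
                            seed = as.integer(opts$seed),
                            out_dir = opts$out)
        }
        0L
      },
      fixtures = {
        nm <- opts$positional[1L]
        if (is.null(nm)) stop("fixture name required", call. = FALSE)
        fx <- load_fixtures(nm)
        if (is.matrix(fx)) {
          utils::write.csv(fx, stdout(), quote = FALSE)
        } else {
          utils::write.csv(fx, stdout(), row.names = FALSE, quote = FALSE)
        }
        0L
      },
      { cat("unknown subcommand: ", cmd, "\n", sep = ""); usage(); 2L })
  }, error = function(e) {
    cat("error: ", conditionMessage(e), "\n", sep = "")
    2L
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
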