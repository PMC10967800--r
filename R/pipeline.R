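# Orchestration: extract -> preprocess -> train -> report.

#' Pipeline configuration
#'
#' Collects every tunable of the extraction and training stages with the
#' study defaults: surface cut 0.30, inclusion filters (length 100-700,
#' mean pLDDT > 50), water probe 1.4 \ifelse{html}{\out{&Aring;}}{A},
#' roughness sweep 1.0-3.6 step 0.2, significance 0.05, collinearity cut
#' 0.8, Cook's rule 4/n with |standardized residual| > 2, five stratified
#' 80/20 splits with five-fold grid-search CV.
#'
#' @param structure_dir Directory of PDB files.
#' @param manifest Path to a CSV with columns `id`, `label` (`HAC` or
#'   `extracellular`), or a data frame.
#' @param output_dir Where to persist CSV/JSON outputs (`NULL`: return
#'   only).
#' @param surface_threshold,min_plddt,min_length,max_length,probe_radius,fd_radii,voxel,n_sphere_points
#'   Extraction settings (see the respective functions).
#' @param alpha,collinearity_threshold,cooks_threshold,resid_threshold
#'   Preprocessing settings.
#' @param algorithms,n_repeats,cv_folds,grids,seeds,train_frac Training
#'   settings (see [compare_models()]).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(structure_dir = NULL, manifest = NULL,
                            output_dir = NULL,
                            surface_threshold = 0.30, min_plddt = 50,
                            min_length = 100, max_length = 700,
                            probe_radius = 1.4,
                            fd_radii = seq(1.0, 3.6, by = 0.2), voxel = 0.5,
                            n_sphere_points = 960,
                            alpha = 0.05, collinearity_threshold = 0.8,
                            cooks_threshold = NULL, resid_threshold = 2.0,
                            algorithms = c("knn", "rf", "svm", "lr"),
                            n_repeats = 5, cv_folds = 5,
                            grids = default_grids(),
                            seeds = seq_len(n_repeats) - 1L,
                            train_frac = 0.8) {
  cfg <- as.list(environment())
  stopifnot(surface_threshold > 0, surface_threshold < 1,
            min_length >= 1, max_length >= min_length,
            probe_radius > 0, voxel <= min(fd_radii),
            alpha > 0, alpha < 1,
            collinearity_threshold > 0, collinearity_threshold <= 1,
            train_frac > 0, train_frac < 1)
  structure(cfg, class = "PipelineConfig")
}

.read_manifest <- function(manifest) {
  if (is.null(manifest)) return(NULL)
  m <- if (is.data.frame(manifest)) manifest else
    read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "label") %in% names(m)))
  lab <- match(tolower(m$label), c("extracellular", "hac")) - 1
  if (anyNA(lab)) stop("manifest labels must be 'HAC' or 'extracellular'")
  stats::setNames(lab, m$id)
}

#' Extract the descriptor table from a directory of structures
#'
#' Reads every `*.pdb` file under `config$structure_dir`, applies the
#' inclusion filters, computes the descriptor vector for each surviving
#' structure and assembles the dataset table, ordered by id.  Unreadable
#' files and filtered structures are logged, not fatal.
#'
#' @param config A [pipeline_config()].
#' @return The descriptor table (see [compute_descriptor_table()]); the
#'   `exclusions` attribute logs every dropped file with its reason.
#'   When `config$output_dir` is set, writes `descriptors.csv` and
#'   `exclusions.csv` there.
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"), !is.null(config$structure_dir))
  files <- sort(list.files(config$structure_dir, pattern = "\\.pdb$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no PDB files in ", config$structure_dir)
  labels <- .read_manifest(config$manifest)
  structures <- list(); excl <- list()
  for (f in files) {
    s <- tryCatch(read_protein_pdb(f), error = function(e) {
      message("skipping unreadable ", basename(f), ": ", conditionMessage(e))
      conditionMessage(e)
    })
    if (is.character(s)) {
      excl[[length(excl) + 1]] <- data.frame(id = basename(f), reason = s)
      next
    }
    flt <- passes_inclusion_filters(s, min_length = config$min_length,
                                    max_length = config$max_length,
                                    min_plddt = config$min_plddt)
    if (!flt$pass) {
      excl[[length(excl) + 1]] <- data.frame(
        id = s$id, reason = paste(flt$reasons, collapse = "; "))
      next
    }
    structures[[length(structures) + 1]] <- s
  }
  tab <- compute_descriptor_table(
    structures, labels = labels,
    probe_radius = config$probe_radius,
    surface_threshold = config$surface_threshold,
    fd_radii = config$fd_radii, voxel = config$voxel,
    n_sphere_points = config$n_sphere_points,
    check_filters = FALSE # config-level filters already applied above
  )
  if (nrow(tab) == 0) stop("no structure survived the inclusion filters")
  exclusions <- rbind(
    if (length(excl) > 0) do.call(rbind, excl) else NULL,
    attr(tab, "exclusions")
  )
  attr(tab, "exclusions") <- exclusions
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(config$output_dir, "descriptors.csv"),
              row.names = FALSE)
    write.csv(exclusions, file.path(config$output_dir, "exclusions.csv"),
              row.names = FALSE)
  }
  tab
}

#' Preprocess and train the classifiers on a descriptor table
#'
#' Runs the full statistical stage: Pearson/collinearity screening,
#' Cook's-distance outlier removal, then repeated stratified model
#' comparison with train-fitted scaling, and Wald odds-ratio inference
#' averaged over the per-split unpenalized logistic fits.  Every seed and
#' dropped-feature decision is recorded in the returned report.
#'
#' @param config A [pipeline_config()].
#' @param table Descriptor table from [run_extract()] (or any data frame
#'   with descriptor columns and a 0/1 `label`).
#' @return List `screen` (kept/dropped descriptors), `outliers` (removed
#'   rows), `evaluation` (a `ModelEvaluation`), `inference` (Wald table),
#'   `config_used` (seeds and thresholds).  When `config$output_dir` is
#'   set, writes `inference.csv` and `metrics.json` there.
#' @export
run_train <- function(config, table) {
  stopifnot(inherits(config, "PipelineConfig"))
  y <- as.numeric(table$label)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("training needs both classes in `label`")
  desc <- intersect(c(DESCRIPTOR_NAMES, attr(table, "descriptors")),
                    names(table))
  x <- table[, desc, drop = FALSE]

  scr <- pearson_screen(x, y, alpha = config$alpha,
                        collinearity_threshold = config$collinearity_threshold)
  kept <- scr$result$kept
  x <- x[, kept, drop = FALSE]

  out <- cooks_outlier_removal(x, y, cooks_threshold = config$cooks_threshold,
                               resid_threshold = config$resid_threshold)
  if (length(out$removed) > 0) {
    x <- x[-out$removed, , drop = FALSE]
    y <- y[-out$removed]
  }

  ev <- compare_models(x, y, algorithms = config$algorithms,
                       n_repeats = config$n_repeats,
                       cv_folds = config$cv_folds, grids = config$grids,
                       seeds = config$seeds, train_frac = config$train_frac)
  inference <- if (length(ev$fits) > 0) wald_report(ev$fits) else NULL

  report <- list(
    screen = scr$result, outliers = out[c("removed", "ids", "threshold")],
    evaluation = ev, inference = inference,
    config_used = list(seeds = config$seeds, alpha = config$alpha,
                       collinearity_threshold = config$collinearity_threshold,
                       resid_threshold = config$resid_threshold,
                       n_repeats = config$n_repeats,
                       cv_folds = config$cv_folds)
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(inference))
      write.csv(inference, file.path(config$output_dir, "inference.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(per_repeat = ev$per_repeat, summary = ev$summary,
           dropped = scr$result$dropped,
           removed_outliers = out$ids,
           seeds = config$seeds),
      file.path(config$output_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  report
}

#' @rdname run_train
#' @export
run_pipeline <- function(config) {
  tab <- run_extract(config)
  res <- run_train(config, tab)
  res$table <- tab
  res
}
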