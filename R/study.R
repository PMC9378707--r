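#' Configuration of an end-to-end study run
#'
#' @param population a [population_spec()] (synthetic mode), or NULL when
#'   reading scans from disk.
#' @param input_dir directory with `scans/*.ply`, matching
#'   `landmarks/<id>.csv` files and `labels.csv` (`specimen_id,group`);
#'   used when `population` is NULL.
#' @param out_dir output directory for the report bundle.
#' @param schedule fitting schedule ([default_fit_schedule()]).
#' @param template_resolution template vertex budget.
#' @param report_threshold_pct contribution cutoff for reported components.
#' @param roc_threshold_pct contribution cutoff for the ROC scan.
#' @param color_threshold loading threshold for colour maps.
#' @param roc_alpha significance level of the ROC scan.
#' @param roc_min_n minimum group size for the ROC scan.
#' @param offset_rounding score-shift rounding rule, see [shift_scores()].
#' @param write_scans also write the generated scans/landmarks (synthetic
#'   mode only).
#' @param resume reuse homologous-model PLYs already present in `out_dir`.
#' @param seed integer; drives every random stage (and overrides the
#'   population spec's seed).
#' @return a `study_config` list.
#' @export
study_config <- function(population = NULL, input_dir = NULL,
                         out_dir = "cranioform_out",
                         schedule = default_fit_schedule(),
                         template_resolution = NULL,
                         report_threshold_pct = 1, roc_threshold_pct = 2,
                         color_threshold = 0.45, roc_alpha = 0.001,
                         roc_min_n = 5L, offset_rounding = "half_up",
                         write_scans = FALSE, resume = FALSE, seed = 1L) {
  if (is.null(population) && is.null(input_dir))
    stop("either a population spec or an input directory is required")
  if (!is.null(population)) stopifnot(inherits(population, "population_spec"))
  if (is.null(template_resolution))
    template_resolution <- if (!is.null(population))
      population$template_resolution else 4500L
  structure(list(population = population, input_dir = input_dir,
                 out_dir = out_dir, schedule = schedule,
                 template_resolution = as.integer(template_resolution),
                 report_threshold_pct = report_threshold_pct,
                 roc_threshold_pct = roc_threshold_pct,
                 color_threshold = color_threshold,
                 roc_alpha = roc_alpha, roc_min_n = as.integer(roc_min_n),
                 offset_rounding = offset_rounding,
                 write_scans = isTRUE(write_scans),
                 resume = isTRUE(resume), seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML mirrors [study_config()] fields; `population:` holds
#' [population_spec()] fields (with `group_offsets` as a list of rows), and
#' `schedule:` is a list with `coarse:` (array of pass maps with keys
#'   `stiffness`, `data_weight`, `landmark_weight`, `max_iter`, `tol`) and
#' `final:` (one pass map).
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  pop <- NULL
  if (!is.null(y$population)) {
    p <- y$population
    if (!is.null(p$group_offsets))
      p$group_offsets <- do.call(rbind, lapply(p$group_offsets, unlist))
    pop <- do.call(population_spec, p)
  }
  sched <- NULL
  if (!is.null(y$schedule)) {
    sched <- list(coarse = lapply(y$schedule$coarse,
                                  function(p) do.call(fit_params, p)),
                  final = do.call(fit_params, y$schedule$final))
  }
  args <- y[setdiff(names(y), c("population", "schedule"))]
  args$population <- pop
  if (!is.null(sched)) args$schedule <- sched
  do.call(study_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full homologous-modelling study
#'
#' Executes the whole pipeline deterministically for a given seed:
#' generate (or load) scans and landmarks; fit the template to every scan;
#' build non-normalized and centroid-size-normalized shape tables and their
#' PCAs; export colour maps, +/-3 SD virtual shapes and group-average
#' models; run the one-vs-rest ROC scan and the allometry scan on both
#' score sets. All tabular outputs are CSV, frames and the run log JSON.
#'
#' @param config a [study_config()].
#' @return (invisibly) a `study_report` list: `models`, `space` /
#'   `space_norm` (`shape_space`s), `fit_qc`, `pca_table`, `roc_table`,
#'   `allometry_table`, `truth` (synthetic mode), `paths`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  out <- config$out_dir
  for (d in c("", "homologous", "color_maps", "virtual_shapes",
              "group_averages"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)

  set.seed(config$seed)
  template <- .stage("template", make_template(config$template_resolution))

  truth <- NULL
  if (!is.null(config$population)) {
    pop <- config$population
    pop$seed <- config$seed
    dat <- .stage("simulate", sample_population(pop))
    scans <- dat$scans; scan_lms <- dat$landmarks
    groups <- dat$truth$group
    truth <- dat$truth
    if (config$write_scans) {
      dir.create(file.path(out, "scans"), showWarnings = FALSE)
      dir.create(file.path(out, "scan_landmarks"), showWarnings = FALSE)
      for (id in names(scans)) {
        write_mesh(scans[[id]], file.path(out, "scans", paste0(id, ".ply")))
        write_landmarks(scan_lms[[id]],
                        file.path(out, "scan_landmarks", paste0(id, ".csv")))
      }
      utils::write.csv(truth, file.path(out, "ground_truth.csv"),
                       row.names = FALSE)
    }
  } else {
    dat <- .stage("load", {
      labels <- utils::read.csv(file.path(config$input_dir, "labels.csv"))
      ids <- labels$specimen_id
      scans <- lapply(ids, function(id)
        read_mesh(file.path(config$input_dir, "scans", paste0(id, ".ply"))))
      lms <- lapply(ids, function(id)
        read_landmarks(file.path(config$input_dir, "landmarks",
                                 paste0(id, ".csv"))))
      list(scans = stats::setNames(scans, ids),
           landmarks = stats::setNames(lms, ids), groups = labels$group)
    })
    scans <- dat$scans; scan_lms <- dat$landmarks; groups <- dat$groups
  }
  ids <- names(scans)

  models <- .stage("fit", {
    lapply(ids, function(id) {
      ply <- file.path(out, "homologous", paste0(id, "_hom.ply"))
      if (config$resume && file.exists(ply)) {
        mesh <- read_mesh(ply)
        frame <- read_head_frame(file.path(out, "homologous",
                                           paste0(id, "_frame.json")))
        lmv <- .lm_vertex_indices(template$mesh, template$landmarks)
        names(lmv) <- landmark_names(template$landmarks)
        # indices are preserved by subdivision, so landmark vertices carry over
        qc <- surface_distance(mesh, to_head_frame(scans[[id]], NULL, frame)$mesh)
        structure(list(mesh = mesh, id = id, frame = frame, qc = qc,
                       centroid_size = centroid_size(mesh),
                       lm_vertices = lmv, topology = .topology_key(mesh),
                       fit_logs = list()),
                  class = "homologous_model")
      } else {
        m <- fit_homologous(template, scans[[id]], scan_lms = scan_lms[[id]],
                            schedule = config$schedule, id = id)
        write_mesh(m$mesh, ply)
        write_head_frame(m$frame, file.path(out, "homologous",
                                            paste0(id, "_frame.json")))
        m
      }
    })
  })
  names(models) <- ids

  fit_qc <- dplyr::bind_rows(lapply(models, function(m)
    dplyr::bind_cols(tibble::tibble(specimen_id = m$id), m$qc,
                     tibble::tibble(centroid_size = m$centroid_size))))
  utils::write.csv(fit_qc, file.path(out, "fit_qc.csv"), row.names = FALSE)

  spaces <- .stage("pca", {
    tab <- build_shape_table(models, normalize_by_cs = FALSE, groups = groups)
    tabn <- build_shape_table(models, normalize_by_cs = TRUE, groups = groups)
    sp <- fit_shape_pca(tab)
    spn <- fit_shape_pca(tabn)
    for (x in list(list(sp, "nonnorm", tab), list(spn, "norm", tabn))) {
      s <- x[[1]]; tag <- x[[2]]
      utils::write.csv(tidy(s),
                       file.path(out, sprintf("pca_table_%s.csv", tag)),
                       row.names = FALSE)
      sc <- data.frame(specimen_id = s$specimen_id, group = s$group,
                       centroid_size = s$centroid_size, s$scores,
                       check.names = FALSE)
      utils::write.csv(sc, file.path(out, sprintf("scores_%s.csv", tag)),
                       row.names = FALSE)
    }
    list(sp = sp, spn = spn, tab = tab, tabn = tabn)
  })
  sp <- spaces$sp; spn <- spaces$spn

  .stage("exports", {
    comps <- select_components(sp, config$roc_threshold_pct)
    for (k in comps) {
      cm <- color_map(sp, spaces$tab, k, threshold = config$color_threshold)
      write_mesh(color_map_mesh(sp, cm),
                 file.path(out, "color_maps", sprintf("PC%d.ply", k)))
      for (ks in c(-3, 3))
        write_mesh(virtual_shape(sp, k, ks),
                   file.path(out, "virtual_shapes",
                             sprintf("PC%d_%+dSD.ply", k, ks)))
    }
    for (gname in unique(groups)) {
      gm <- group_average_model(models[groups == gname])
      write_mesh(gm, file.path(out, "group_averages",
                               paste0(gname, ".ply")))
    }
  })

  roc_table <- .stage("roc", {
    rt <- one_vs_rest_scan(sp, alpha = config$roc_alpha,
                           min_n = config$roc_min_n)
    utils::write.csv(rt, file.path(out, "roc_table.csv"), row.names = FALSE)
    rt
  })

  allometry_table <- .stage("allometry", {
    cs <- vapply(models, `[[`, 0, "centroid_size")  # non-normalized sizes
    at <- dplyr::bind_rows(
      allometry_scan(sp, cs, config$report_threshold_pct,
                     config$offset_rounding),
      allometry_scan(spn, cs, config$report_threshold_pct,
                     config$offset_rounding))
    utils::write.csv(at, file.path(out, "allometry_table.csv"),
                     row.names = FALSE)
    at
  })

  .stage("log", {
    sched <- config$schedule
    jsonlite::write_json(list(
      seed = config$seed,
      template = list(resolution = config$template_resolution,
                      vertices = n_vertices(template$mesh),
                      faces = n_faces(template$mesh)),
      schedule = list(coarse = lapply(sched$coarse, unclass),
                      final = unclass(sched$final)),
      conventions = list(
        centroid_size = "all homologous-model vertices",
        covariance = "sample covariance, N-1, no standardization",
        loading = "Pearson correlation of coordinate with score",
        component_sign = "largest-|loading| coordinate loads positive",
        normalization = "per-specimen division by own centroid size",
        offset_rounding = config$offset_rounding,
        roc_alpha = config$roc_alpha, roc_min_n = config$roc_min_n,
        report_threshold_pct = config$report_threshold_pct,
        roc_threshold_pct = config$roc_threshold_pct,
        color_threshold = config$color_threshold)),
      file.path(out, "run_log.json"), auto_unbox = TRUE, digits = NA)
  })

  invisible(structure(list(models = models, space = sp, space_norm = spn,
                           fit_qc = fit_qc,
                           pca_table = tidy(sp),
                           roc_table = roc_table,
                           allometry_table = allometry_table,
                           truth = truth,
                           paths = list(out = out)),
                      class = "study_report"))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d specimens; outputs in %s\n",
              length(x$models), x$paths$out))
  invisible(x)
}
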