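# Full virtual-study orchestration: generate the clavicle population, place
# every plate on every clavicle, realize the 2-examiner x 2-trial
# repeatability design by jittered re-placements, measure fragment metrics,
# and run the inferential layer.

#' Virtual study configuration
#'
#' Defaults encode the study design: 10 clavicles, 2 examiners x 2 trials
#' (40 placement records per plate), lateral fragment sizes 10-30 mm in
#' 5 mm steps, a 3 mm TOST equivalence margin, and alpha = 0.05.
#'
#' @param population a [population_spec()].
#' @param plates character vector of fixture names.
#' @param fragment_sizes mm, positive ascending.
#' @param examiners,trials design counts.
#' @param jitter a [jitter_spec()] (its seed is re-derived per record).
#' @param placement a [placement_config()] (its seed is re-derived per task).
#' @param tost_margin mm equivalence margin.
#' @param alpha_level significance level.
#' @param master_seed integer; all per-task seeds derive from it.
#' @param mesh_resolution axial segments of the generated bone meshes.
#' @export
study_config <- function(population = population_spec(),
                         plates = c("distal_radial_8", "lateral_extension_6",
                                    "straight_6"),
                         fragment_sizes = c(10, 15, 20, 25, 30),
                         examiners = 2L, trials = 2L,
                         jitter = jitter_spec(),
                         placement = placement_config(),
                         tost_margin = 3,
                         alpha_level = 0.05,
                         master_seed = 0L,
                         mesh_resolution = 72L) {
  stopifnot(all(diff(fragment_sizes) > 0), all(fragment_sizes > 0),
            examiners * trials >= 1)
  structure(list(population = population, plates = plates,
                 fragment_sizes = fragment_sizes,
                 examiners = as.integer(examiners),
                 trials = as.integer(trials),
                 jitter = jitter, placement = placement,
                 tost_margin = tost_margin, alpha_level = alpha_level,
                 master_seed = as.integer(master_seed),
                 mesh_resolution = as.integer(mesh_resolution)),
            class = "study_config")
}

#' Derive a reproducible sub-seed from a master seed and a task label
#'
#' Simple multiplicative string hash folded into [0, 2^31 - 2]; gives
#' independent, parallel-safe streams per (module, plate, clavicle,
#' examiner, trial) task.
#'
#' @param master_seed integer.
#' @param ... label components (coerced to character).
#' @return integer seed.
#' @export
split_seed <- function(master_seed, ...) {
  lab <- paste(c(master_seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Run the full virtual plate-placement study
#'
#' Generates the synthetic population, measures the fan angles of every
#' plate fixture, places each plate on each clavicle (examiner 1 / trial 1 =
#' optimizer output; the other examiner x trial cells are constraint-checked
#' jittered realizations of it), traces screws, counts contained screws per
#' fragment size, measures covered areas, and runs the TOST / Steel-Dwass /
#' Tukey analyses. Fully deterministic under `master_seed`.
#'
#' @param cfg a [study_config()].
#' @param verbose print progress.
#' @return list of class `study_report` with `angle_table`, `placements`
#'   (data frame), `count_table`, `area_table`, `repeatability_table`,
#'   `count_tests`, `area_test`, `config`, and the generated `population`
#'   and `records`.
#' @export
run_study <- function(cfg = study_config(), verbose = FALSE) {
  ms <- cfg$master_seed
  pop_spec <- cfg$population
  pop_spec$seed <- split_seed(ms, "population")
  population <- sample_population(pop_spec,
                                  mesh_resolution = cfg$mesh_resolution)
  plates <- lapply(cfg$plates, make_plate_fixture)
  names(plates) <- cfg$plates

  angle_table <- do.call(rbind, lapply(plates, function(p) {
    fa <- measure_fan_angles(p)
    data.frame(plate = p$name, n_screws = length(p$screws),
               alpha = fa$alpha, beta = fa$beta)
  }))
  rownames(angle_table) <- NULL

  cells <- expand.grid(examiner = seq_len(cfg$examiners),
                       trial = seq_len(cfg$trials))
  records <- list()
  rows <- list()
  for (plate in plates) {
    for (clav in population) {
      if (verbose) message("placing ", plate$name, " on ", clav$id)
      pcfg <- cfg$placement
      pcfg$seed <- split_seed(ms, "place", plate$name, clav$id)
      base <- place_plate(clav, plate, pcfg, examiner_id = 1L, trial_id = 1L)
      for (ci in seq_len(nrow(cells))) {
        ex <- cells$examiner[ci]; tr <- cells$trial[ci]
        rec <- if (ex == 1 && tr == 1) base else {
          js <- cfg$jitter
          js$seed <- split_seed(ms, "jitter", plate$name, clav$id, ex, tr)
          jitter_placement(base, js, clavicle = clav, plate = plate,
                           cfg = pcfg, examiner_id = ex, trial_id = tr)
        }
        traces <- trace_screws(clav, plate, rec$transform)
        counts <- vapply(cfg$fragment_sizes, function(fs) {
          count_contained(traces, axial_plane_at(clav, fs))
        }, integer(1))
        area25 <- covered_area(traces, plate, max_dist_from_acj = 25)
        area_all <- covered_area(traces, plate)
        key <- paste(plate$name, clav$id, ex, tr, sep = "_")
        records[[key]] <- list(placement = rec, traces = traces,
                               counts = counts)
        row <- data.frame(plate = plate$name, clavicle = clav$id,
                          examiner = ex, trial = tr,
                          acj_distance = rec$acj_distance,
                          gap_rms = rec$gap_rms,
                          covered_area = as.numeric(area25),
                          covered_area_all = as.numeric(area_all))
        for (si in seq_along(cfg$fragment_sizes)) {
          row[[paste0("n_screws_", cfg$fragment_sizes[si])]] <- counts[si]
        }
        rows[[key]] <- row
      }
    }
  }
  placements <- do.call(rbind, rows)
  rownames(placements) <- NULL

  count_table <- do.call(rbind, lapply(cfg$plates, function(pn) {
    do.call(rbind, lapply(cfg$fragment_sizes, function(fs) {
      v <- placements[placements$plate == pn, paste0("n_screws_", fs)]
      data.frame(plate = pn, fragment_size = fs, mean = mean(v),
                 sd = stats::sd(v), n = length(v))
    }))
  }))
  area_table <- do.call(rbind, lapply(cfg$plates, function(pn) {
    v <- placements$covered_area[placements$plate == pn]
    data.frame(plate = pn, mean = mean(v), sd = stats::sd(v), n = length(v))
  }))

  # repeatability: trial 1 vs 2 within each examiner, examiner 1 vs 2 means
  rep_rows <- list()
  for (pn in cfg$plates) {
    sub <- placements[placements$plate == pn, ]
    pick <- function(ex, tr) {
      s <- sub[sub$examiner == ex & sub$trial == tr, ]
      s$acj_distance[order(s$clavicle)]
    }
    comps <- list()
    if (cfg$trials >= 2 && pop_spec$n >= 2) {
      for (ex in seq_len(cfg$examiners)) {
        comps[[sprintf("examiner%d_trial1_vs_trial2", ex)]] <-
          list(a = pick(ex, 1), b = pick(ex, 2))
      }
    }
    if (cfg$examiners >= 2 && pop_spec$n >= 2) {
      exmean <- function(ex) {
        s <- sub[sub$examiner == ex, ]
        tapply(s$acj_distance, s$clavicle, mean)
      }
      m1 <- exmean(1); m2 <- exmean(2)
      comps[["examiner1_vs_examiner2"]] <-
        list(a = as.numeric(m1), b = as.numeric(m2[names(m1)]))
    }
    for (cn in names(comps)) {
      eq <- tost_equivalence(comps[[cn]]$a, comps[[cn]]$b,
                             margin = cfg$tost_margin)
      rep_rows[[paste(pn, cn)]] <- data.frame(
        plate = pn, comparison = cn, mean_abs_diff = eq$mean_abs_diff,
        ci_low = eq$ci_low, ci_high = eq$ci_high, p_tost = eq$p_tost,
        p_tost_abs = eq$p_tost_abs, n = eq$n)
    }
  }
  repeatability_table <- if (length(rep_rows) > 0) {
    out <- do.call(rbind, rep_rows)
    rownames(out) <- NULL
    out
  } else NULL
  insufficient_n <- cfg$examiners * cfg$trials * pop_spec$n < 2

  count_groups <- function(fs) {
    g <- lapply(cfg$plates, function(pn) {
      placements[placements$plate == pn, paste0("n_screws_", fs)]
    })
    names(g) <- cfg$plates
    g
  }
  count_tests <- if (!insufficient_n && length(cfg$plates) >= 2) {
    out <- lapply(cfg$fragment_sizes, function(fs) steel_dwass(count_groups(fs)))
    names(out) <- paste0("fragment_", cfg$fragment_sizes)
    out
  } else NULL
  area_test <- if (!insufficient_n && length(cfg$plates) >= 2) {
    g <- lapply(cfg$plates, function(pn) {
      placements$covered_area[placements$plate == pn]
    })
    names(g) <- cfg$plates
    tukey_hsd(g)
  } else NULL

  structure(list(angle_table = angle_table, placements = placements,
                 count_table = count_table, area_table = area_table,
                 repeatability_table = repeatability_table,
                 count_tests = count_tests, area_test = area_test,
                 insufficient_n = insufficient_n,
                 population = population, records = records, config = cfg),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf(" %d plates x %d clavicles x %d examiners x %d trials = %d records/plate\n",
              length(x$config$plates), x$config$population$n,
              x$config$examiners, x$config$trials,
              x$config$population$n * x$config$examiners * x$config$trials))
  cat("\nFan angles (degrees):\n")
  print(x$angle_table, row.names = FALSE)
  cat("\nContained screws (mean over records):\n")
  print(x$count_table, row.names = FALSE)
  cat("\nCovered area on the inferior cortex within 25 mm of the ACJ (mm^2):\n")
  print(x$area_table, row.names = FALSE)
  invisible(x)
}

#' Write the study report as CSV/JSON tables
#'
#' @param report a `study_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    angles = file.path(dir, "angle_table.csv"),
    placements = file.path(dir, "placements.csv"),
    counts = file.path(dir, "count_table.csv"),
    areas = file.path(dir, "area_table.csv"),
    repeatability = file.path(dir, "repeatability_table.csv"))
  utils::write.csv(report$angle_table, paths["angles"], row.names = FALSE)
  utils::write.csv(report$placements, paths["placements"], row.names = FALSE)
  utils::write.csv(report$count_table, paths["counts"], row.names = FALSE)
  utils::write.csv(report$area_table, paths["areas"], row.names = FALSE)
  if (!is.null(report$repeatability_table)) {
    utils::write.csv(report$repeatability_table, paths["repeatability"],
                     row.names = FALSE)
  }
  pj <- file.path(dir, "pairwise_tests.json")
  jsonlite::write_json(list(
    count_tests = lapply(report$count_tests, function(t) {
      list(labels = t$labels, p = t$p, statistic = t$statistic)
    }),
    area_test = if (!is.null(report$area_test)) {
      list(labels = report$area_test$labels, p = report$area_test$p,
           statistic = report$area_test$statistic)
    }), pj, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(c(paths, pairwise = pj))
}
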