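trace_columns <- c("trial", "digit", "sample", "t",
                   "F_x", "F_y", "F_z", "M_x", "M_y", "M_z")

#' Write force/torque traces to a delimited file
#'
#' Long-format, tab-separated, UTF-8, "." decimal; one row per sample per
#' digit with columns `trial`, `digit`, `sample` (0-based), `t` (s),
#' `F_x`, `F_y`, `F_z` (N), `M_x`, `M_y`, `M_z` (N m). Lines starting with
#' `#` carry provenance and are skipped on read.
#'
#' @param trials list of trials, each a list with `thumb` and `index`
#'   [ft_trace()]s (as returned by [simulate_trial()]), or a single such
#'   trial.
#' @param path output file.
#' @param provenance optional named character vector written as `# key: value`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_traces <- function(trials, path, provenance = NULL) {
  if (!is.null(trials$thumb)) trials <- list(trials)
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    do.call(rbind, lapply(list(tr$thumb, tr$index), function(d) {
      data.frame(trial = i, digit = d$digit,
                 sample = seq_along(d$t) - 1L, t = d$t,
                 F_x = d$F[, "x"], F_y = d$F[, "y"], F_z = d$F[, "z"],
                 M_x = d$M[, "x"], M_y = d$M[, "y"], M_z = d$M[, "z"],
                 stringsAsFactors = FALSE)
    }))
  })
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  }
  utils::write.table(do.call(rbind, rows), con, sep = "\t", dec = ".",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read force/torque traces written by [write_traces()]
#'
#' Validates the schema: all required columns present (a missing column is
#' reported by name), per (trial, digit) sample indices contiguous from 0,
#' and a constant sampling interval.
#'
#' @param path input file.
#' @param calibration list with `rotation` and per-digit `pad_offset_x`
#'   (named numeric, `thumb` and `index`), attached to the traces.
#' @param aligned whether the stored traces are already in the common
#'   frame.
#' @return list of trials, each a list with `thumb` and `index`
#'   [ft_trace()]s.
#' @export
read_traces <- function(path,
                        calibration = list(rotation = diag(3),
                                           pad_offset_x = c(thumb = -0.01,
                                                            index = 0.01)),
                        aligned = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(trace_columns, names(df))
  if (length(missing_cols)) {
    heftr_error("heftr_schema_error",
                paste0("trace file missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  out <- lapply(sort(unique(df$trial)), function(tr) {
    one <- lapply(c("thumb", "index"), function(dg) {
      d <- df[df$trial == tr & df$digit == dg, ]
      d <- d[order(d$sample), ]
      if (!nrow(d)) {
        heftr_error("heftr_schema_error",
                    sprintf("trial %s has no '%s' samples", tr, dg))
      }
      if (!identical(as.integer(d$sample), seq_len(nrow(d)) - 1L)) {
        heftr_error("heftr_schema_error",
                    sprintf("trial %s digit %s: sample indices not contiguous from 0",
                            tr, dg))
      }
      ft_trace(dg, d$t, as.matrix(d[c("F_x", "F_y", "F_z")]),
               as.matrix(d[c("M_x", "M_y", "M_z")]),
               calibration = list(rotation = calibration$rotation,
                                  pad_offset_x = unname(calibration$pad_offset_x[dg])),
               aligned = aligned)
    })
    names(one) <- c("thumb", "index")
    one
  })
  out
}

#' Expand CoM-pointing judgments into per-half ratings
#'
#' Converts each CoM-task row of a rating table into two half-rating rows
#' via [com_to_half_ratings()], attaching the material labels of the
#' corresponding object halves. Non-CoM rows pass through unchanged.
#'
#' @param ratings rating table (see [simulate_ratings()]).
#' @param objects named list of [object_spec()]s keyed by `object_id`.
#' @return expanded rating table.
#' @export
expand_com_ratings <- function(ratings, objects) {
  is_com <- ratings$task == "com"
  if (!any(is_com)) return(ratings)
  com <- ratings[is_com, ]
  expanded <- do.call(rbind, lapply(seq_len(nrow(com)), function(i) {
    row <- com[i, ]
    obj <- objects[[row$object_id]]
    pair <- com_to_half_ratings(row$raw, L = obj$length)
    out <- row[c(1, 1), ]
    out$target <- c("half1", "half2")
    out$material <- obj$appearance
    out$raw <- as.numeric(pair)
    out
  }))
  out <- rbind(ratings[!is_com, ], expanded)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic-experiment pipeline
#'
#' Simulates a session (design, perceptual ratings and optionally full
#' force/torque traces), then runs the complete analysis chain: kinetic
#' dependent variables per trial, per-participant rating standardization,
#' illusion indices, a one-sample t-test of the post-lift index against
#' zero, and the competing-priors regime predictions. Deterministic given
#' `design$seed`.
#'
#' @param design a [design_spec()].
#' @param lift a [lift_params()] used for trace simulation.
#' @param observer a [synthetic_observer()]; its task is overridden per
#'   participant by `tasks`.
#' @param tasks character vector recycled over participants (default
#'   `"numeric"`), e.g. `c("numeric", "com")` for the two judgment groups.
#' @param heavy_label,light_label material labels defining the illusion
#'   index.
#' @param kinetics simulate and analyze force/torque traces (slower).
#' @param out_dir optional directory; when given, tidy result tables are
#'   written as tab-separated files with provenance headers.
#' @return list with `design`, `ratings`, `indices`, `index_test`,
#'   `kinetics`, `regimes`.
#' @export
run_pipeline <- function(design, lift = lift_params(),
                         observer = synthetic_observer(),
                         tasks = "numeric",
                         heavy_label = "granite", light_label = "styrofoam",
                         kinetics = FALSE, out_dir = NULL) {
  stopifnot(inherits(design, "design_spec"))
  trials <- make_design(design)
  objects <- stats::setNames(design$objects,
                             vapply(design$objects, `[[`, "", "id"))
  practice_obj <- object_spec(0.2, 0.2, appearance = c("oak", "oak"),
                              id = "practice")
  seed <- design$seed

  ratings <- list()
  for (p in seq_len(design$n_participants)) {
    obs <- observer
    obs$task <- tasks[(p - 1) %% length(tasks) + 1]
    prows <- trials[trials$participant == p, ]
    # practice ratings anchor the participant's scale
    for (k in seq_len(design$practice_trials)) {
      ratings[[length(ratings) + 1L]] <-
        simulate_ratings(obs, practice_obj, "post", 1,
                         seed = derive_seed(seed, p, 900 + k),
                         participant = p)
    }
    # one pre-lift (expectation) rating per object
    for (oid in names(objects)) {
      ratings[[length(ratings) + 1L]] <-
        simulate_ratings(obs, objects[[oid]], "pre", 1,
                         seed = derive_seed(seed, p, match(oid, names(objects))),
                         participant = p)
    }
    # post-lift rating after every main trial
    main <- prows[prows$phase == "main", ]
    for (i in seq_len(nrow(main))) {
      ratings[[length(ratings) + 1L]] <-
        simulate_ratings(obs, objects[[main$object_id[i]]], "post", 1,
                         seed = derive_seed(seed, p, 100 + main$trial[i]),
                         participant = p)
    }
  }
  ratings <- do.call(rbind, ratings)
  ratings <- expand_com_ratings(ratings, c(objects, list(practice = practice_obj)))
  ratings <- zscore_by_participant(ratings)

  kin <- NULL
  if (kinetics) {
    main <- trials[trials$phase == "main", ]
    kin <- do.call(rbind, lapply(seq_len(nrow(main)), function(i) {
      obj <- objects[[main$object_id[i]]]
      sim <- simulate_trial(obj, lift,
                            seed = derive_seed(seed, main$participant[i],
                                               500 + main$trial[i]))
      res <- analyze_trial(sim$thumb, sim$index, obj)
      data.frame(participant = main$participant[i], trial = main$trial[i],
                 object_id = obj$id,
                 peak_torque_Nmm = res$peak_torque_y,
                 peak_GF_N = res$peak_gf, peak_GFR_Ns = res$peak_gfr,
                 peak_LF_N = res$peak_lf, peak_LFR_Ns = res$peak_lfr,
                 holding_median_torque_Nmm = res$holding_median_torque_y,
                 stringsAsFactors = FALSE)
    }))
  }

  idx <- illusion_index(ratings[ratings$material %in% c(heavy_label, light_label) &
                                  !is.na(ratings$material), ],
                        heavy_label, light_label)
  index_test <- if (nrow(idx) >= 2) t_tests(idx$post, kind = "one-sample") else NULL
  regimes <- predict_all_regimes()

  out <- list(design = trials, ratings = ratings, indices = idx,
              index_test = index_test, kinetics = kin, regimes = regimes,
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- c(package = paste0("heftr ", utils::packageVersion("heftr")),
              seed = as.character(seed))
    wt <- function(d, f) {
      con <- file(file.path(out_dir, f), "w", encoding = "UTF-8")
      on.exit(close(con), add = TRUE)
      for (k in names(prov)) writeLines(sprintf("# %s: %s", k, prov[[k]]), con)
      utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
    }
    wt(trials, "design.tsv")
    wt(ratings, "ratings.tsv")
    wt(idx, "illusion_indices.tsv")
    if (!is.null(kin)) wt(kin, "kinetics.tsv")
    wt(regimes, "regime_predictions.tsv")
  }
  out
}
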