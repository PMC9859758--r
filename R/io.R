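#' Pipeline configuration
#'
#' Conventions used throughout: frames are 0-based, time in seconds, lengths
#' in micrometres, intensities in arbitrary units (with exposure recorded
#' where relevant); segment endpoints are inclusive. Tab-separated tables
#' with a header are canonical; comma-separated input is accepted.
#'
#' @param dt Frame interval, s (default 3.5).
#' @param annotation An [annotation_config()].
#' @param loss_window_s Window for punctum-loss frequency, s (default 175).
#' @param seed Integer seed recorded in the run manifest, or `NULL`.
#' @param verbose Emit progress messages to standard error.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(dt = 3.5, annotation = annotation_config(),
                            loss_window_s = 175, seed = NULL,
                            verbose = FALSE) {
  if (dt <= 0) stop_invalid("dt must be > 0")
  structure(list(dt = dt, annotation = annotation,
                 loss_window_s = loss_window_s, seed = seed,
                 verbose = verbose),
            class = "pipeline_config")
}

read_table_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.delim(path, sep = sep, na.strings = c("NA", ""),
             stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read punctum tracking tables
#'
#' Reads a TSV/CSV of per-frame punctum--SPB distances and intensities and
#' splits it into validated per-punctum trajectories. Mandatory columns:
#' `cell_id`, `punctum_id`, `strain`, `frame`, `time_s`, `length_um`,
#' `intensity_au`; empty cells are missing values. Frames within a
#' trajectory must be strictly increasing with no duplicates; violations
#' are reported with the offending rows.
#'
#' @param path Path to the tracks file.
#' @return A named list of trajectory `data.frame`s (one per
#'   cell/punctum/strain combination).
#' @export
read_tracks <- function(path) {
  d <- read_table_auto(path)
  need <- c("cell_id", "punctum_id", "strain", "frame", "time_s",
            "length_um", "intensity_au")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop_invalid("tracks file lacks mandatory column(s): ",
                 paste(miss, collapse = ", "))
  if (!"lost" %in% names(d)) d$lost <- FALSE
  d$.row <- seq_len(nrow(d)) + 1L            # header is line 1
  key <- paste(d$cell_id, d$punctum_id, d$strain, sep = "\r")
  split_d <- split(d, factor(key, levels = unique(key)))
  out <- lapply(split_d, function(tr) {
    dup <- duplicated(tr$frame)
    if (any(dup))
      stop_invalid("duplicate frame(s) for ", tr$cell_id[1], "/",
                   tr$punctum_id[1], " at file line(s) ",
                   paste(tr$.row[dup], collapse = ", "))
    if (is.unsorted(tr$frame, strictly = TRUE))
      stop_invalid("frames not strictly increasing for ", tr$cell_id[1], "/",
                   tr$punctum_id[1])
    tr$.row <- NULL
    rownames(tr) <- NULL
    tr
  })
  names(out) <- vapply(out, function(tr)
    paste(tr$cell_id[1], tr$punctum_id[1], tr$strain[1], sep = "/"),
    character(1))
  out
}

#' Write trajectories to a tracks table
#'
#' @param trajectories A list of trajectory `data.frame`s or a single
#'   combined `data.frame`.
#' @param path Output path (TSV; missing values as empty cells).
#' @return The path, invisibly.
#' @export
write_tracks <- function(trajectories, path) {
  d <- if (is.data.frame(trajectories)) trajectories
       else do.call(rbind, lapply(trajectories, function(tr) {
         tr[intersect(c("cell_id", "punctum_id", "strain", "frame", "time_s",
                        "length_um", "intensity_au", "lost"), names(tr))]
       }))
  write_tsv(d, path)
}

#' Write an annotation segment table
#'
#' One row per segment, keyed by cell, punctum and strain; columns
#' `start_frame`, `end_frame` (0-based inclusive), `kind`, `slope`,
#' `intercept`, `slope_p`, `n_points`.
#'
#' @param segments A combined segment `data.frame` (see [run_pipeline()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_segments <- function(segments, path) write_tsv(segments, path)

#' Read a segment table written by [write_segments()]
#' @param path Path to the segments file.
#' @return A `data.frame`.
#' @export
read_segments <- function(path) read_table_auto(path)

#' Read a phase-separation grid table
#'
#' Columns `protein_uM`, `nacl_mM`, `separated` (0/1 or logical).
#'
#' @param path Path to the grid file.
#' @return A validated phase-grid `data.frame`.
#' @export
read_phase_grid <- function(path) validate_phase_grid(read_table_auto(path))

#' Write a phase grid or binodal table
#' @param x A phase grid or `"binodal"` `data.frame`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phase_table <- function(x, path) write_tsv(as.data.frame(x), path)

#' Read droplet fusion events
#'
#' Columns `event_id`, `frame`, `time_s`, `L_um`, `W_um`; returns one
#' `data.frame` per event.
#'
#' @param path Path to the droplets file.
#' @return A named list of fusion-event `data.frame`s.
#' @export
read_fusion_events <- function(path) {
  d <- read_table_auto(path)
  need <- c("event_id", "time_s", "L_um", "W_um")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop_invalid("droplets file lacks column(s): ", paste(miss, collapse = ", "))
  lapply(split(d, factor(d$event_id, levels = unique(d$event_id))),
         function(e) { rownames(e) <- NULL; e })
}

#' Run the trajectory analysis pipeline
#'
#' Annotates every trajectory, pools growth and shrinkage partial
#' trajectories, fits the joint mixed-effects rate models per response and
#' phase, and summarizes punctum-loss frequency. Deterministic given inputs
#' and configuration; a run manifest records the configuration and package
#' version.
#'
#' @param trajectories A list of trajectory `data.frame`s (from
#'   [read_tracks()] or [simulate_trajectory()]).
#' @param config A [pipeline_config()].
#' @return A list of class `"tip_pipeline"`: `segments` (combined keyed
#'   segment table), `annotations`, `lme_fits` (per response/phase, `NULL`
#'   where too few partials), `lme_table` (combined fixed-effect table),
#'   `loss` (a `"loss_summary"`), `manifest`.
#' @export
run_pipeline <- function(trajectories, config = pipeline_config()) {
  msg <- function(...) if (config$verbose) message(...)
  manifest <- list(package = "tipquant",
                   version = as.character(utils::packageVersion("tipquant")),
                   seed = config$seed, dt = config$dt,
                   n_trajectories = length(trajectories),
                   annotation = unclass(config$annotation))
  if (length(trajectories) == 0) {
    return(structure(list(segments = data.frame(), annotations = list(),
                          lme_fits = list(), lme_table = data.frame(),
                          loss = NULL, manifest = manifest),
                     class = "tip_pipeline"))
  }
  msg("annotating ", length(trajectories), " trajectories")
  anns <- lapply(trajectories, annotate_trajectory, config = config$annotation)
  seg_rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    cbind(data.frame(cell_id = tr$cell_id[1], punctum_id = tr$punctum_id[1],
                     strain = tr$strain[1]), anns[[i]]$segments)
  })
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL

  lme_fits <- list()
  lme_rows <- list()
  for (resp in c("length", "intensity")) {
    partials <- extract_partials(trajectories, anns, response = resp,
                                 config = config$annotation)
    for (ph in c("growth", "shrinkage")) {
      p <- partials[partials$phase == ph, , drop = FALSE]
      key <- paste(resp, ph, sep = "_")
      if (length(unique(p$partial_id)) < 2) {
        lme_fits[[key]] <- NULL
        next
      }
      msg("fitting mixed model: ", key, " (", nrow(p), " observations)")
      fit <- fit_lme(p)
      lme_fits[[key]] <- fit
      if (isTRUE(fit$converged))
        lme_rows[[key]] <- cbind(data.frame(response = resp, phase = ph),
                                 fit$fixed)
    }
  }
  lme_table <- if (length(lme_rows) > 0) {
    x <- do.call(rbind, lme_rows); rownames(x) <- NULL; x
  } else data.frame()

  loss <- loss_frequency(trajectories, window_s = config$loss_window_s)
  structure(list(segments = segments, annotations = anns,
                 lme_fits = lme_fits, lme_table = lme_table, loss = loss,
                 manifest = manifest),
            class = "tip_pipeline")
}
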