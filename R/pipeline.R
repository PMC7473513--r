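# End-to-end pipeline: detect -> traces -> fit -> report.

#' Pipeline configuration
#'
#' @param channels named list of channel inputs: each of `gag`, `early`,
#'   `late` is either a [movie_stack()] or a path to a TIFF stack.
#' @param dt frame interval (s) of the ESCRT channels.
#' @param psf_sigma PSF sigma (px).
#' @param background nominal background (a.u./pixel), metadata only.
#' @param condition condition label attached to outputs.
#' @param threshold_snr,max_displacement,coloc_radius detection stage
#'   parameters.
#' @param aperture,annulus,target photometry stage parameters.
#' @param scale optional shared normalization scale factor (overrides the
#'   cohort-derived one; used to compare conditions on one scale).
#' @param delay_threshold phenotype delay threshold (s).
#' @param overlap_s fit-window overlap into the plateau (s).
#' @param seed pipeline seed (bootstrap etc.).
#' @param out_dir output directory or `NULL` for in-memory only.
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(channels, dt = 0.2, psf_sigma = 1.3,
                            background = 100, condition = "WT",
                            threshold_snr = 5, max_displacement = 2,
                            coloc_radius = 2, aperture = 4,
                            annulus = c(6, 9), target = 10000,
                            scale = NULL, delay_threshold = 5,
                            overlap_s = 2, seed = 1, out_dir = NULL) {
  if (dt <= 0) stop_invalid("dt must be > 0")
  need <- c("gag", "early", "late")
  if (!all(need %in% names(channels))) {
    stop_invalid("channels must name gag, early and late inputs")
  }
  for (ch in need) {
    x <- channels[[ch]]
    if (is.character(x) && !file.exists(x)) {
      stop_invalid("channel file does not exist: ", x)
    } else if (!is.character(x) && !inherits(x, "MovieStack")) {
      stop_invalid("channel '", ch, "' must be a path or a MovieStack")
    }
  }
  structure(
    list(channels = channels, dt = dt, psf_sigma = psf_sigma,
         background = background, condition = condition,
         threshold_snr = threshold_snr, max_displacement = max_displacement,
         coloc_radius = coloc_radius, aperture = aperture, annulus = annulus,
         target = target, scale = scale, delay_threshold = delay_threshold,
         overlap_s = overlap_s, seed = seed, out_dir = out_dir),
    class = "PipelineConfig"
  )
}

load_channel <- function(x, channel, dt, psf_sigma, background) {
  if (inherits(x, "MovieStack")) return(x)
  arr <- read_tiff_stack(x)
  nf <- dim(arr)[3]
  times <- if (channel == "gag" && nf == 2L) {
    c(0, NA) # patched by caller once ESCRT frame count is known
  } else {
    (seq_len(nf) - 1) * dt
  }
  movie_stack(arr, times, channel, psf_sigma, background)
}

#' Run the full analysis pipeline
#'
#' Stages: spot detection on the start/end Gag frames and site building;
#' colocalization of each valid site against the ESCRT channels'
#' mean projections; aperture photometry per site and channel; cohort
#' normalization; three-phase segmentation and Boltzmann fitting;
#' phenotype classification; cohort summary. All stage outputs are
#' returned and, when `out_dir` is set, written as CSV/JSON together
#' with a manifest of every parameter.
#'
#' @param config a [pipeline_config()].
#' @return list with `sites`, `traces` (list of [intensity_trace()]),
#'   `scale`, `fits`, `phenotypes`, `summary`, `qc` (warnings table).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  gag <- load_channel(config$channels$gag, "gag", config$dt,
                      config$psf_sigma, config$background)
  early <- load_channel(config$channels$early, "early", config$dt,
                        config$psf_sigma, config$background)
  late <- load_channel(config$channels$late, "late", config$dt,
                       config$psf_sigma, config$background)
  if (!all(dim(gag$data)[1:2] == dim(early$data)[1:2]) ||
      !all(dim(early$data)[1:2] == dim(late$data)[1:2])) {
    stop_invalid("channel stacks disagree on image geometry")
  }
  if (anyNA(gag$times)) {
    gag$times <- early$times[c(1L, length(early$times))]
  }
  qc <- list()
  note <- function(stage, msg) {
    qc[[length(qc) + 1L]] <<- data.frame(stage = stage, message = msg)
  }

  # --- detection ------------------------------------------------------
  nf_gag <- dim(gag$data)[3]
  det_start <- detect_spots(gag$data[, , 1L], config$psf_sigma,
                            config$threshold_snr)
  det_end <- detect_spots(gag$data[, , nf_gag], config$psf_sigma,
                          config$threshold_snr)
  sites <- build_event_sites(det_start, det_end, config$max_displacement)
  valid <- sites[sites$status == "valid", , drop = FALSE]
  if (nrow(valid) == 0L) note("detection", "no valid sites")

  # --- colocalization -------------------------------------------------
  proj <- function(m) apply(m$data, c(1, 2), mean)
  det_early <- detect_spots(proj(early), config$psf_sigma, config$threshold_snr)
  det_late <- detect_spots(proj(late), config$psf_sigma, config$threshold_snr)
  coloc <- vapply(seq_len(nrow(valid)), function(i) {
    colocalize(valid[i, ], det_early, config$coloc_radius)$colocalized &&
      colocalize(valid[i, ], det_late, config$coloc_radius)$colocalized
  }, logical(1))
  valid$colocalized <- coloc

  # --- photometry -----------------------------------------------------
  traces <- list()
  for (i in seq_len(nrow(valid))) {
    for (m in list(early, late)) {
      tr <- tryCatch(
        extract_trace(m, valid[i, ], config$aperture, config$annulus),
        ek_validation_error = function(e) {
          note("photometry", conditionMessage(e)); NULL
        })
      if (!is.null(tr)) traces[[length(traces) + 1L]] <- tr
    }
  }
  if (length(traces) == 0L) stop_invalid("no traces extracted")
  norm <- normalize_traces(traces, config$target, scale = config$scale)
  traces <- norm$traces

  # --- kinetics -------------------------------------------------------
  fits <- lapply(traces, function(tr) {
    fit_event(tr, overlap_s = config$overlap_s)
  })

  # --- phenotyping ----------------------------------------------------
  by_site <- split(fits, vapply(fits, function(f) as.numeric(f$site_id),
                                numeric(1)))
  phenotypes <- lapply(by_site, function(fs) {
    chs <- vapply(fs, `[[`, character(1), "channel")
    if (!all(c("early", "late") %in% chs)) {
      return(structure(list(site_id = fs[[1]]$site_id,
                            class = "unclassifiable", delay_s = NA_real_,
                            max_early = NA_real_, max_late = NA_real_,
                            scale = fs[[1]]$scale,
                            reason = "channel trace missing"),
                       class = "EventPhenotype"))
    }
    classify_event(fs[[which(chs == "early")[1]]],
                   fs[[which(chs == "late")[1]]],
                   config$delay_threshold)
  })
  summary <- summarize_cohort(fits, phenotypes)

  result <- list(sites = sites, traces = traces, scale = norm$scale,
                 fits = fits, phenotypes = phenotypes, summary = summary,
                 qc = if (length(qc)) do.call(rbind, qc) else
                   data.frame(stage = character(0), message = character(0)),
                 config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.csv(result$sites, p("sites.csv"), row.names = FALSE)
  long <- do.call(rbind, lapply(result$traces, function(tr) {
    data.frame(site_id = tr$site_id, channel = tr$channel,
               frame = seq_along(tr$time) - 1L, time_s = tr$time,
               raw = tr$raw, background = tr$background,
               normalized = tr$normalized)
  }))
  utils::write.csv(long, p("traces.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(result$fits, kinetic_fit_row)),
                   p("fits.csv"), row.names = FALSE)
  ph <- do.call(rbind, lapply(result$phenotypes, function(x) {
    data.frame(site_id = x$site_id, class = x$class, delay_s = x$delay_s,
               max_early = x$max_early, max_late = x$max_late,
               reason = x$reason)
  }))
  utils::write.csv(ph, p("phenotypes.csv"), row.names = FALSE)
  utils::write.csv(result$qc, p("qc.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = unclass(result$summary), scale = result$scale),
    p("summary.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- c(
    list(package_version = as.character(utils::packageVersion("escrtkinetics")),
         scale = result$scale),
    config[setdiff(names(config), "channels")],
    list(channels = lapply(config$channels, function(x) {
      if (is.character(x)) x else "in-memory MovieStack"
    }))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(result)
}
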