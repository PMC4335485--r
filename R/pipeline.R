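# Pipeline orchestration and file formats. Tables travel as TSV, aperture
# masks as a compact plain-text container, configurations as YAML and stage
# manifests as JSON, so every artifact is inspectable and diffable.

#' Pipeline configuration
#'
#' Assembles (or loads from YAML) the configuration governing a full
#' synthetic mapping session: display geometry, stimulus design, sheet and
#' noise parameters, fitting thresholds and the single global seed from
#' which every stochastic stage derives its RNG state.
#'
#' @param path optional YAML file; entries override the defaults below.
#' @param ... named overrides applied after the file.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    display = list(max_ecc = 9, pixels_per_degree = 2),
    design = list(),
    sheet = list(n_vertices = 100, sigma_intercept = 0.5,
                 sigma_slope = 0.25, roi = "V1"),
    noise = list(cnr = 3, ar1_rho = 0),
    fitting = list(coarse_incl_r2 = 0.05, analysis_r2 = 0.1,
                   fwhm_prf_mm = 8.3, fwhm_phase_mm = 5,
                   xy_step = 2.4, n_sigma = 34,
                   sigma_min = 0.32, sigma_max = 32),
    tr_s = 2.55,
    seed = 1
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  structure(cfg, class = "pipeline_config")
}

#' Write / read an aperture sequence as plain text
#'
#' A self-describing text container: a JSON header line with timing, design
#' and grid metadata, followed by one row of 0/1 characters per volume
#' (pixels in grid order).
#'
#' @param ap an \code{aperture_sequence}.
#' @param path output file.
#' @export
write_apertures <- function(ap, path) {
  header <- jsonlite::toJSON(list(
    condition = ap$condition, direction = ap$direction, tr_s = ap$tr_s,
    max_ecc_deg = ap$grid$max_ecc_deg,
    pixels_per_degree = ap$grid$pixels_per_degree,
    n_volumes = nrow(ap$masks), is_blank = ap$is_blank
  ), auto_unbox = TRUE)
  rows <- apply(ap$masks, 1, function(r) paste(as.integer(r), collapse = ""))
  writeLines(c(as.character(header), rows), path)
  invisible(path)
}

#' @rdname write_apertures
#' @return \code{read_apertures} returns the reconstructed
#'   \code{aperture_sequence}.
#' @export
read_apertures <- function(path) {
  lines <- readLines(path)
  h <- jsonlite::fromJSON(lines[1])
  g <- vf_grid(h$max_ecc_deg, h$pixels_per_degree)
  masks <- do.call(rbind, lapply(lines[-1], function(r) {
    as.integer(strsplit(r, "")[[1]]) > 0L
  }))
  new_aperture_sequence(masks, h$tr_s, h$condition, h$direction,
                        h$is_blank, g)
}

#' Write / read a tabular result as TSV
#'
#' @param x data frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the synthetic mapping pipeline
#'
#' Executes the requested stages end to end on a synthetic cortical sheet:
#' \describe{
#'   \item{stimuli}{generate aperture sequences for all conditions}
#'   \item{simulate}{simulate BOLD series from the sheet's ground truth}
#'   \item{hrf}{estimate the HRF from the simulated photic run}
#'   \item{prf}{coarse-to-fine pRF fitting per condition}
#'   \item{phase}{phase-encoded analysis of the wedge-and-ring runs}
#'   \item{crossval}{cross-validated comparison of training conditions}
#'   \item{report}{threshold fits and tabulate size-eccentricity summaries}
#' }
#' Each stage writes its outputs under \code{out_dir} and is recorded in a
#' JSON manifest (parameters, files, MD5 checksums). Stage dependencies are
#' checked and a missing prerequisite names the stage to run first.
#'
#' @param config a \code{pipeline_config}.
#' @param stages character subset of the stages above, in any order.
#' @param out_dir output directory (created if needed).
#' @param verbose log stage progress.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("stimuli", "simulate", "hrf", "prf",
                                    "phase", "crossval", "report"),
                         out_dir = tempfile("prfmap_"), verbose = FALSE) {
  all_stages <- c("stimuli", "simulate", "hrf", "prf", "phase", "crossval",
                  "report")
  stages <- intersect(all_stages, stages)
  deps <- list(simulate = "stimuli", hrf = "simulate", prf = "hrf",
               phase = "simulate", crossval = "prf", report = "prf")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !need %in% stages) {
      stop(sprintf("stage '%s' requires stage '%s'; run it first", s, need))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list())
  env <- new.env()

  add_stage <- function(name, params, files) {
    manifest$stages[[name]] <<- list(
      parameters = params,
      files = as.list(stats::setNames(
        unname(tools::md5sum(files)), basename(files)))
    )
  }

  if ("stimuli" %in% stages) {
    stage_log(verbose, "stage stimuli")
    cfg <- carrier_config(config$display$max_ecc,
                          config$display$pixels_per_degree)
    design <- do.call(stimulus_design, config$design)
    env$runs <- session_schedule(design, cfg, config$tr_s)
    env$photic <- photic_sequence(cfg, config$tr_s)
    env$design <- design
    env$cfg <- cfg
    f <- file.path(out_dir, "apertures_wedge_ring_fwd.txt")
    write_apertures(env$runs$wedge_ring_fwd, f)
    add_stage("stimuli", list(max_ecc = cfg$max_ecc_deg,
                              total_volumes = attr(env$runs, "total_volumes")),
              f)
  }

  if ("simulate" %in% stages) {
    stage_log(verbose, "stage simulate")
    sh <- config$sheet
    env$sheet <- make_sheet(
      sh$n_vertices,
      rois = list(roi_spec(sh$roi, sh$sigma_intercept, sh$sigma_slope)),
      max_ecc = config$display$max_ecc, seed = config$seed
    )
    env$hrf_true <- hrf_params(dt = config$tr_s)
    ns <- function(off) noise_spec(config$noise$cnr, config$noise$ar1_rho,
                                   seed = config$seed + off)
    env$data <- list(
      bar = simulate_bold(env$sheet,
                          env$runs[c("bar_card_fwd", "bar_obli_fwd")],
                          env$hrf_true, ns(1)),
      wedge_ring_fwd = simulate_bold(env$sheet,
                                     env$runs$wedge_ring_fwd,
                                     env$hrf_true, ns(2)),
      wedge_ring_rev = simulate_bold(env$sheet,
                                     env$runs$wedge_ring_rev,
                                     env$hrf_true, ns(3)),
      photic = simulate_bold(env$sheet, env$photic, env$hrf_true, ns(4))
    )
    f <- file.path(out_dir, "ground_truth.tsv")
    write_tsv(env$sheet$truth, f)
    add_stage("simulate", list(n_vertices = env$sheet$n_vertices,
                               cnr = config$noise$cnr, seed = config$seed),
              f)
  }

  if ("hrf" %in% stages) {
    stage_log(verbose, "stage hrf")
    env$hrf_est <- estimate_hrf(env$data$photic, env$photic)
    env$kernel <- double_gamma(env$hrf_est)
    f <- file.path(out_dir, "hrf_params.tsv")
    write_tsv(data.frame(response_delay = env$hrf_est$response_delay,
                         undershoot_delay = env$hrf_est$undershoot_delay,
                         ratio = env$hrf_est$ratio,
                         amplitude = env$hrf_est$amplitude,
                         rsq = env$hrf_est$rsq,
                         reliable = env$hrf_est$reliable), f)
    add_stage("hrf", list(reliable = env$hrf_est$reliable), f)
  }

  if ("prf" %in% stages) {
    stage_log(verbose, "stage prf")
    ft <- config$fitting
    env$fits <- list()
    files <- character(0)
    for (cond in c("bar", "wedge_ring_fwd")) {
      runs <- if (cond == "bar") {
        env$runs[c("bar_card_fwd", "bar_obli_fwd")]
      } else env$runs["wedge_ring_fwd"]
      grid <- build_search_grid(runs, env$kernel, xy_step = ft$xy_step,
                                sigma_range = c(ft$sigma_min, ft$sigma_max),
                                n_sigma = ft$n_sigma)
      env$fits[[cond]] <- fit_prf(env$data[[cond]], env$sheet, grid,
                                  fwhm_mm = ft$fwhm_prf_mm,
                                  incl_r2 = ft$coarse_incl_r2)
      f <- file.path(out_dir, sprintf("prf_fits_%s.tsv", cond))
      write_tsv(env$fits[[cond]], f)
      files <- c(files, f)
    }
    add_stage("prf", list(xy_step = ft$xy_step, n_sigma = ft$n_sigma),
              files)
  }

  if ("phase" %in% stages) {
    stage_log(verbose, "stage phase")
    env$phase <- phase_encode(env$data$wedge_ring_fwd,
                              env$data$wedge_ring_rev,
                              env$runs$wedge_ring_fwd, env$sheet,
                              fwhm_mm = config$fitting$fwhm_phase_mm)
    f <- file.path(out_dir, "phase_map.tsv")
    write_tsv(as.data.frame(env$phase), f)
    add_stage("phase", list(fwhm_mm = config$fitting$fwhm_phase_mm), f)
  }

  if ("crossval" %in% stages) {
    stage_log(verbose, "stage crossval")
    target <- env$runs[c("bar_card_rev", "bar_obli_rev")]
    obs <- simulate_bold(env$sheet, target, env$hrf_true,
                         noise_spec(config$noise$cnr, config$noise$ar1_rho,
                                    seed = config$seed + 5))
    rows <- lapply(names(env$fits), function(cond) {
      pred <- predict_heldout(env$fits[[cond]], target, env$kernel)
      fz <- fisher_z_scores(pred, obs, env$sheet$roi)
      cbind(fz$by_roi, condition = cond)
    })
    env$crossval <- do.call(rbind, rows)
    f <- file.path(out_dir, "crossval.tsv")
    write_tsv(env$crossval, f)
    add_stage("crossval", list(), f)
  }

  if ("report" %in% stages) {
    stage_log(verbose, "stage report")
    thr <- threshold_fits(cbind(env$fits$bar, roi = env$sheet$roi),
                          r2_min = config$fitting$analysis_r2)
    curve <- bin_sigma_by_eccentricity(thr, bin_deg = 1,
                                       max_ecc = config$display$max_ecc)
    f <- file.path(out_dir, "sigma_by_eccentricity.tsv")
    write_tsv(curve, f)
    add_stage("report", list(analysis_r2 = config$fitting$analysis_r2), f)
  }

  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$path <- out_dir
  invisible(manifest)
}
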