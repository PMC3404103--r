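#' Ordinary least-squares fit of endpoint projection versus scan distance
#'
#' Fits `s_endpoint ~ d` over the points whose d lies inside `d_window`.
#' The default window 5-11 Angstrom covers the near-linear regime; the
#' 12-Angstrom point is excluded by default because filter over-stretching
#' marks a different regime there.
#'
#' @param points data.frame with columns `d` and `s_endpoint`.
#' @param d_window `c(lo, hi)` in Angstrom.
#' @return list with `slope`, `intercept`, `residuals` (named by d),
#'   `d_window`, `n`.
#' @export
linear_fit <- function(points, d_window = c(5, 11)) {
  keep <- points$d >= d_window[1] & points$d <= d_window[2]
  if (sum(keep) < 2) {
    stop("linear fit needs at least 2 scan points inside the window [",
         d_window[1], ", ", d_window[2], "]")
  }
  fit <- lm(s_endpoint ~ d, data = points[keep, , drop = FALSE])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       residuals = setNames(unname(residuals(fit)), points$d[keep]),
       d_window = d_window, n = sum(keep))
}

.load_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1) {
    base <- dirname(manifest)
    man <- if (grepl("\\.json$", manifest)) {
      if (!requireNamespace("jsonlite", quietly = TRUE)) {
        stop("jsonlite needed for JSON manifests")
      }
      jsonlite::read_json(manifest, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(manifest)
    }
    attr(man, "base_dir") <- base
    man
  } else {
    manifest
  }
}

.resolve_model <- function(x, base_dir) {
  if (inherits(x, "structure_model")) return(x)
  p <- if (!is.null(base_dir) && !file.exists(x)) file.path(base_dir, x) else x
  read_pdb(p)
}

.resolve_traj <- function(x, base_dir) {
  if (inherits(x, "trajectory")) return(x)
  p <- if (!is.null(base_dir) && !file.exists(x)) file.path(base_dir, x) else x
  tr <- read_pdb(p)
  if (!inherits(tr, "trajectory")) stop(p, " is not a multi-model PDB")
  tr
}

#' Run the distance-scan analysis pipeline
#'
#' Orchestrates the full scan: for every group of trajectories sharing a
#' restraint-distance label d it computes the post-burn-in endpoint
#' projection on the conductive-to-collapsed coordinate, the realized mean
#' CB-CB distance (d is only the scan label; the realized separation is
#' re-measured and reported alongside), an RMSF summary of the SF carbonyl
#' oxygens, and the intra-/inter-subunit H-bond fractions of the focal
#' residue; it then fits `s_endpoint` versus d over the declared window.
#'
#' The manifest (a list, or path to a YAML/JSON file with paths relative to
#' it) carries: `refs$conductive`, `refs$collapsed` (models or PDB paths),
#' `selection` (reaction-coordinate atoms), `groups` (each with `d` and
#' `trajectories`), and optionally `burn_in` (ps, default 40000),
#' `cb_pair`, `focal_resnum`, `fit_window`, `rmsf_measure`, `rmsf_align`.
#'
#' @param manifest manifest list or file path.
#' @param out_dir optional directory for TSV output tables.
#' @param verbose print stage messages to standard error.
#' @return a `scan_report`: list with `points` (one row per d, sorted),
#'   `endpoints` (per run), `fit` (or NULL for a single point), and the
#'   parameters used.
#' @export
run_scan <- function(manifest, out_dir = NULL, verbose = FALSE) {
  man <- .load_manifest(manifest)
  base <- attr(man, "base_dir")
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)

  # fail fast: every referenced file must exist before any computation
  paths <- character(0)
  for (x in c(list(man$refs$conductive, man$refs$collapsed),
              unlist(lapply(man$groups, `[[`, "trajectories"),
                     recursive = FALSE))) {
    if (is.character(x)) {
      p <- if (!is.null(base) && !file.exists(x)) file.path(base, x) else x
      paths <- c(paths, p)
    }
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "))
  }
  if (!length(man$groups)) stop("manifest has no trajectory groups")

  burn_in <- if (is.null(man$burn_in)) 40000 else man$burn_in
  selection <- if (is.null(man$selection)) {
    "resnum 624-628 and name N CA C O"
  } else man$selection
  fit_window <- if (is.null(man$fit_window)) c(5, 11) else
    as.numeric(man$fit_window)
  rmsf_measure <- if (is.null(man$rmsf_measure)) {
    "resnum 624-627 and name O"
  } else man$rmsf_measure
  rmsf_align <- if (is.null(man$rmsf_align)) selection else man$rmsf_align
  cb_pair <- if (is.null(man$cb_pair)) {
    list(a = list(resnum = 620, atom = "CB"),
         b = list(resnum = 629, atom = "CB"))
  } else man$cb_pair
  focal <- if (is.null(man$focal_resnum)) 629 else man$focal_resnum

  say("building reaction coordinate (", selection, ")")
  refA <- .resolve_model(man$refs$conductive, base)
  refB <- .resolve_model(man$refs$collapsed, base)
  rc <- build_reaction_coordinate(refA, refB, selection)

  endpoint_rows <- list(); point_rows <- list()
  for (g in man$groups) {
    d <- as.numeric(g$d)
    say("group d = ", d, " (", length(g$trajectories), " run(s))")
    s_runs <- numeric(0); d_meas <- numeric(0); rmsf_runs <- numeric(0)
    fr_intra <- numeric(0); fr_inter <- numeric(0)
    for (r in seq_along(g$trajectories)) {
      tr <- .resolve_traj(g$trajectories[[r]], base)
      s_bar <- endpoint_projection(tr, rc, burn_in = burn_in)
      s_runs <- c(s_runs, s_bar)
      endpoint_rows[[length(endpoint_rows) + 1L]] <-
        data.frame(d = d, run = r, s_endpoint = s_bar)
      dm <- vapply(seq_len(n_frames(tr)), function(i) {
        mean(pair_distance_by_chain(tr, a = .pair_spec(cb_pair$a),
                                    b = .pair_spec(cb_pair$b), frame = i))
      }, numeric(1))
      d_meas <- c(d_meas, mean(dm))
      pr <- rmsf(tr, rmsf_measure, rmsf_align)
      rmsf_runs <- c(rmsf_runs, mean(pr$atoms$rmsf))
      hb <- hbond_series(tr, focal_resnum = focal)
      cf <- contact_fraction(hb)
      fr_intra <- c(fr_intra, cf$intra_fraction[1])
      fr_inter <- c(fr_inter, cf$inter_fraction[1])
    }
    point_rows[[length(point_rows) + 1L]] <- data.frame(
      d_target = d, d_measured = mean(d_meas),
      s_endpoint = mean(s_runs),
      s_endpoint_sem = if (length(s_runs) > 1) {
        sd(s_runs) / sqrt(length(s_runs))
      } else NA_real_,
      rmsf_mean = mean(rmsf_runs),
      intra_fraction = mean(fr_intra), inter_fraction = mean(fr_inter),
      n_runs = length(s_runs))
  }
  points <- do.call(rbind, point_rows)
  points <- points[order(points$d_target), , drop = FALSE]
  rownames(points) <- NULL
  endpoints <- do.call(rbind, endpoint_rows)

  fit <- NULL
  fit_pts <- data.frame(d = points$d_target, s_endpoint = points$s_endpoint)
  if (sum(fit_pts$d >= fit_window[1] & fit_pts$d <= fit_window[2]) >= 2) {
    fit <- linear_fit(fit_pts, fit_window)
  } else {
    say("fewer than 2 points in the fit window: no linear fit")
  }
  report <- structure(list(points = points, endpoints = endpoints, fit = fit,
                           params = list(burn_in = burn_in,
                                         selection = selection,
                                         fit_window = fit_window,
                                         rmsf_measure = rmsf_measure,
                                         rmsf_align = rmsf_align,
                                         focal_resnum = focal)),
                      class = "scan_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(points, file.path(out_dir, "scan_points.tsv"), report$params)
    write_tsv(endpoints, file.path(out_dir, "endpoints.tsv"), report$params)
    if (!is.null(fit)) {
      write_tsv(data.frame(slope = fit$slope, intercept = fit$intercept,
                           window_lo = fit_window[1],
                           window_hi = fit_window[2], n = fit$n),
                file.path(out_dir, "linear_fit.tsv"), report$params)
    }
  }
  report
}

.pair_spec <- function(x) list(resnum = x$resnum, atom = x$atom)

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("<scan_report> %d scan point(s), burn-in %g ps\n",
              nrow(x$points), x$params$burn_in))
  print(x$points, row.names = FALSE)
  if (!is.null(x$fit)) {
    cat(sprintf("linear fit over d = %g-%g A: slope %.4f, intercept %.4f\n",
                x$fit$d_window[1], x$fit$d_window[2],
                x$fit$slope, x$fit$intercept))
  }
  invisible(x)
}

#' Write a TSV table with header comments
#'
#' Output convention of the pipeline: `#`-prefixed header lines record the
#' analysis parameters and package version, followed by a tab-separated
#' table.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("sfcollapse")),
                  error = function(e) "dev")
  writeLines(sprintf("# sfcollapse %s", ver), con)
  for (nm in names(params)) {
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(params[[nm]]), collapse = " ")), con)
  }
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' Read a pipeline TSV
#' @param path TSV path written by [write_tsv()].
#' @return data.frame (header comments dropped).
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", sep = "\t", header = TRUE)
}

#' @export
plot.scan_report <- function(x, ...) {
  p <- x$points
  graphics::plot(p$d_target, p$s_endpoint, pch = 19,
                 xlab = "restraint distance d (A)",
                 ylab = "endpoint projection s", ...)
  if (!is.null(x$fit)) graphics::abline(x$fit$intercept, x$fit$slope, lty = 2)
  if (any(is.finite(p$s_endpoint_sem))) {
    graphics::arrows(p$d_target, p$s_endpoint - p$s_endpoint_sem,
                     p$d_target, p$s_endpoint + p$s_endpoint_sem,
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}
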