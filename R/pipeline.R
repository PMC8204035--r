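#' Run the full eruption-assessment workflow on one case
#'
#' End-to-end pipeline: rigid MI registration of the follow-up scan onto the
#' baseline over the stable-bone ROI, resampling, registration validation by
#' part comparison over the ROI, tooth segmentation in both scans (threshold
#' band or supplied contours), and ICP-based motion decomposition into the
#' six clinical components.
#'
#' @param pre,post [image_volume]s (baseline and follow-up) or file paths
#'   readable by [read_volume].
#' @param roi [roi_box] over stable bone, in baseline world mm.
#' @param frame [anatomical_frame] of the tooth. Required before any
#'   computation starts.
#' @param tooth_band length-2 intensity band for threshold segmentation of
#'   the tooth; or supply `contours`.
#' @param bone_band length-2 intensity band for the part-comparison surfaces.
#' @param contours optional list of [slice_contour]s for the baseline tooth
#'   (used instead of `tooth_band` for the baseline; the follow-up tooth then
#'   also needs `contours_post`).
#' @param contours_post optional contours for the registered follow-up tooth.
#' @param reg_params [registration_params].
#' @param icp [icp_params].
#' @param out_dir optional directory: writes transform.txt, post_reg.mha,
#'   tooth_pre.stl, tooth_post.stl, measures.json (with a provenance block)
#'   and mad.json.
#' @return list of class `eruption_case`: `measures`, `mad` (part-comparison
#'   report), `transform`, `pre_tooth`, `post_tooth`, `provenance`.
#' @export
run_case <- function(pre, post, roi, frame, tooth_band = NULL,
                     bone_band = NULL, contours = NULL, contours_post = NULL,
                     reg_params = registration_params(), icp = icp_params(),
                     out_dir = NULL) {
  if (missing(frame) || !inherits(frame, "anatomical_frame"))
    stop("configuration error: an anatomical frame is required")
  if (!inherits(roi, "roi_box"))
    stop("configuration error: a stable-region ROI box is required")
  if (is.null(tooth_band) && is.null(contours))
    stop("configuration error: supply a tooth intensity band or contours")
  if (!is.null(contours) && is.null(contours_post))
    stop("configuration error: contour segmentation needs contours for both scans")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.character(pre)) pre <- stage("read pre", read_volume(pre))
  if (is.character(post)) post <- stage("read post", read_volume(post))
  reg <- stage("registration",
               register_rigid_mi(pre, post, roi, reg_params))
  post_reg <- stage("resampling", resample(post, reg, pre))
  mad_report <- if (!is.null(bone_band))
    stage("part comparison",
          part_comparison(crop_to_roi(pre, roi), crop_to_roi(post_reg, roi),
                          bone_band))
  else NULL
  if (is.null(contours)) {
    pre_tooth <- stage("segmentation (pre)", auto_segment(pre, tooth_band))
    post_tooth <- stage("segmentation (post)", auto_segment(post_reg, tooth_band))
  } else {
    pre_tooth <- stage("segmentation (pre)",
                       mesh_from_mask(interpolate_contours(contours, pre)))
    post_tooth <- stage("segmentation (post)",
                        mesh_from_mask(interpolate_contours(contours_post, pre)))
  }
  measures <- stage("eruption analysis",
                    assess_eruption(pre_tooth, post_tooth, frame, icp))
  prov <- list(package = "erupt3d",
               version = as.character(utils::packageVersion("erupt3d")),
               date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
               registration = reg_params[setdiff(names(reg_params), "init")],
               icp = unclass(icp),
               tooth_band = tooth_band, bone_band = bone_band,
               roi = unclass(roi), side = frame$side, cleft = frame$cleft)
  out <- structure(list(measures = measures, mad = mad_report, transform = reg,
                        pre_tooth = pre_tooth, post_tooth = post_tooth,
                        provenance = prov),
                   class = "eruption_case")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_transform(rigid_transform(unclass(reg)), file.path(out_dir, "transform.txt"))
    write_volume(post_reg, file.path(out_dir, "post_reg.mha"))
    write_stl(pre_tooth, file.path(out_dir, "tooth_pre.stl"))
    write_stl(post_tooth, file.path(out_dir, "tooth_post.stl"))
    jsonlite::write_json(
      c(list(measures = as.data.frame(measures)),
        if (!is.null(mad_report)) list(mad = mad_report$mad, sd = mad_report$sd),
        list(provenance = prov)),
      file.path(out_dir, "measures.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  out
}

#' @export
print.eruption_case <- function(x, ...) {
  print(x$measures)
  if (!is.null(x$mad))
    cat(sprintf("registration part comparison: MAD %.4f +/- %.4f mm (%d vertices)\n",
                x$mad$mad, x$mad$sd, x$mad$n))
  invisible(x)
}

#' Run a cohort of cases and summarize per side
#'
#' Applies [run_case] to each case, collects the six components per case, and
#' reports mean +/- SD per component per side plus a Wilcoxon signed-rank
#' comparison of cleft versus non-cleft sides per component when both sides
#' are present (paired by case order). Per-case failures are reported and the
#' statistics computed on the survivors.
#'
#' @param cases list of argument lists for [run_case]; each may carry an
#'   element `side_label` (`"cleft"`/`"non-cleft"`) and `case_id`.
#' @return list of class `cohort_report`: `table` (per-case components),
#'   `stats` (mean/SD per side), `wilcoxon` (per component, if applicable),
#'   `failures`.
#' @export
run_cohort <- function(cases) {
  if (length(cases) < 1) stop("no cases")
  rows <- list()
  failures <- list()
  for (i in seq_along(cases)) {
    args <- cases[[i]]
    side_label <- args$side_label %||% "unlabelled"
    case_id <- args$case_id %||% i
    args$side_label <- NULL; args$case_id <- NULL
    res <- tryCatch(do.call(run_case, args), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(case = case_id,
                                               reason = conditionMessage(res))
      next
    }
    rows[[length(rows) + 1]] <- cbind(data.frame(case = case_id, side = side_label),
                                      as.data.frame(res$measures))
  }
  if (length(rows) == 0) stop("no case survived; all failed")
  tab <- do.call(rbind, rows)
  comps <- c("dMD", "dPF", "dIA", "pitch", "roll", "yaw")
  stats_list <- list()
  for (s in unique(tab$side)) {
    sub <- tab[tab$side == s, ]
    for (cc in comps) {
      sm <- summarize_values(sub[[cc]])
      stats_list[[length(stats_list) + 1]] <-
        data.frame(side = s, component = cc, mean = sm$mean, sd = sm$sd,
                   abs_mean = sm$abs_mean, n = sm$n,
                   sd_undefined = sm$sd_undefined)
    }
  }
  wil <- NULL
  if (all(c("cleft", "non-cleft") %in% tab$side)) {
    a <- tab[tab$side == "cleft", ]
    b <- tab[tab$side == "non-cleft", ]
    m <- min(nrow(a), nrow(b))
    wil <- do.call(rbind, lapply(comps, function(cc) {
      w <- tryCatch(wilcoxon_signed_rank(a[[cc]][seq_len(m)], b[[cc]][seq_len(m)]),
                    error = function(e) NULL)
      data.frame(component = cc,
                 W = if (is.null(w)) NA_real_ else w$statistic,
                 p_value = if (is.null(w)) NA_real_ else w$p_value)
    }))
  }
  structure(list(table = tab, stats = do.call(rbind, stats_list),
                 wilcoxon = wil, failures = failures,
                 n_survivors = length(rows), n_total = length(cases)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort: %d/%d cases analyzed\n", x$n_survivors, x$n_total))
  s <- x$stats
  s[, c("mean", "sd", "abs_mean")] <- round(s[, c("mean", "sd", "abs_mean")], 3)
  print(s, row.names = FALSE)
  if (!is.null(x$wilcoxon)) {
    cat("cleft vs non-cleft (Wilcoxon signed rank):\n")
    print(x$wilcoxon, row.names = FALSE)
  }
  if (length(x$failures)) cat(length(x$failures), "case(s) failed\n")
  invisible(x)
}
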