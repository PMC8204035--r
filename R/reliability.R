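#' Observer emulation settings
#'
#' A software artifact has no human raters, so the reliability study is
#' re-enacted by emulating the operator-dependent steps: the hand-cropped
#' registration region (the ROI box faces are shrunk inward by up to
#' `roi_shrink` mm), the registration starting pose (perturbed by up to
#' `init_trans` mm / `init_rot` degrees per axis), and the livewire anchor
#' clicks (jittered by up to `anchor_jitter` voxels). `scale` multiplies all
#' amplitudes at once.
#'
#' @param init_trans,init_rot initialization perturbation amplitudes
#'   (mm, degrees).
#' @param roi_shrink inward ROI face jitter amplitude (mm).
#' @param anchor_jitter livewire anchor jitter amplitude (voxels).
#' @param scale overall multiplier.
#' @export
observer_emulation <- function(init_trans = 0.5, init_rot = 0.5,
                               roi_shrink = 0.3, anchor_jitter = 1,
                               scale = 1) {
  structure(list(init_trans = init_trans * scale, init_rot = init_rot * scale,
                 roi_shrink = roi_shrink * scale,
                 anchor_jitter = anchor_jitter * scale),
            class = "observer_emulation")
}

# one emulated-observer pass over one phantom pair
.observer_run <- function(pair, pert, run_seed, segmentation = "livewire",
                          reg_params = registration_params(),
                          icp = icp_params()) {
  spec <- pair$spec
  ints <- spec$intensities
  bone_band <- c((ints["background"] + ints["bone"]) / 2,
                 (ints["bone"] + ints["tooth"]) / 2)
  tooth_band <- c((ints["bone"] + ints["tooth"]) / 2, Inf)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(run_seed)
  roi <- roi_box(pair$roi$lower + runif(3, 0, pert$roi_shrink),
                 pair$roi$upper - runif(3, 0, pert$roi_shrink))
  init <- make_rigid(
    axis_angle_to_rotation(runif(3, -pert$init_rot, pert$init_rot) * pi / 180),
    t = runif(3, -pert$init_trans, pert$init_trans))
  reg_params$init <- init
  reg <- register_rigid_mi(pair$pre, pair$post, roi, reg_params)
  post_reg <- resample(pair$post, reg, pair$pre)
  pre_roi <- crop_to_roi(pair$pre, pair$roi)
  post_roi <- crop_to_roi(post_reg, pair$roi)
  pc <- part_comparison(pre_roi, post_roi, bone_band)
  if (segmentation == "livewire") {
    jit <- pert$anchor_jitter
    pre_tooth <- segment_tooth_livewire(pair$pre, tooth_band, jitter_vox = jit,
                                        seed = run_seed + 1L)
    post_tooth <- segment_tooth_livewire(post_reg, tooth_band, jitter_vox = jit,
                                         seed = run_seed + 2L)
  } else {
    pre_tooth <- auto_segment(pair$pre, tooth_band)
    post_tooth <- auto_segment(post_reg, tooth_band)
  }
  # the ICP vertex subsample is an internal numeric choice, not an operator
  # action: keep it fixed so zero perturbation gives bit-identical runs
  meas <- assess_eruption(pre_tooth, post_tooth, pair$frame, icp)
  list(measures = meas, part_mad = pc$mad, roi_surface = pc$mesh,
       post_roi_surface = threshold_segment(post_roi, bone_band[1], bone_band[2]),
       transform = reg)
}

#' Simulated inter-run reliability study on phantom pairs
#'
#' Runs the full pipeline (stable-region registration, tooth segmentation,
#' motion decomposition) `n_runs` times per phantom pair, each run with an
#' independently seeded observer emulation, and summarizes agreement between
#' runs in the layout of an inter-observer reliability table: ICC(2,1) with
#' 95 percent CI plus the between-run mean absolute difference (MAD) and SD,
#' for the registration part comparison and for the pooled translational and
#' rotational outcome components.
#'
#' @param pairs list of `phantom_pair` objects (>= 2).
#' @param n_runs emulated observer runs per pair (default 2).
#' @param perturbation an [observer_emulation].
#' @param seed master seed; every run's stream derives from it.
#' @param segmentation `"livewire"` (anchor-jittered contouring) or `"band"`
#'   (deterministic thresholding).
#' @return A `reliability_report`: `summary` data.frame (rows: part
#'   comparison / translational / rotational; columns: icc, icc_lo, icc_hi,
#'   mad, sd), `per_component` data.frame, the raw `ratings` matrices,
#'   `part_between_mad` per case, and `failed` (voided cases with reasons).
#' @export
reliability_harness <- function(pairs, n_runs = 2,
                                perturbation = observer_emulation(),
                                seed = 1L, segmentation = c("livewire", "band")) {
  segmentation <- match.arg(segmentation)
  if (length(pairs) < 2) stop("need at least 2 phantom pairs")
  n <- length(pairs)
  comps <- c("dMD", "dPF", "dIA", "pitch", "roll", "yaw")
  ratings <- lapply(comps, function(...) matrix(NA_real_, n, n_runs))
  names(ratings) <- comps
  part <- matrix(NA_real_, n, n_runs)
  part_between <- rep(NA_real_, n)
  failed <- list()
  for (i in seq_len(n)) {
    surfaces <- vector("list", n_runs)
    ok <- TRUE
    for (r in seq_len(n_runs)) {
      run_seed <- as.integer(seed) + 97L * i + 7919L * r
      res <- tryCatch(
        .observer_run(pairs[[i]], perturbation, run_seed, segmentation),
        error = function(e) e)
      if (inherits(res, "error")) {
        failed[[length(failed) + 1]] <- list(case = i, run = r,
                                             reason = conditionMessage(res))
        ok <- FALSE
        break
      }
      for (cc in comps) ratings[[cc]][i, r] <- res$measures[[cc]]
      part[i, r] <- res$part_mad
      # the run-specific surface is the *registered follow-up* one; the
      # baseline surface is shared by construction
      surfaces[[r]] <- res$post_roi_surface
    }
    if (ok && n_runs >= 2) {
      dm <- surface_distance_map(surfaces[[1]], surfaces[[2]])
      part_between[i] <- mad_sd(dm)$mad
    }
  }
  keep <- stats::complete.cases(part)
  icc_safe <- function(m) {
    out <- tryCatch(icc(m), error = function(e) NULL)
    if (is.null(out)) list(icc = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                           degenerate = TRUE)
    else c(out, degenerate = FALSE)
  }
  between_diffs <- function(m) {
    d <- numeric(0)
    for (r1 in seq_len(ncol(m) - 1))
      for (r2 in (r1 + 1):ncol(m))
        d <- c(d, abs(m[, r1] - m[, r2]))
    d
  }
  per_comp <- do.call(rbind, lapply(comps, function(cc) {
    m <- ratings[[cc]][keep, , drop = FALSE]
    ic <- icc_safe(m)
    d <- between_diffs(m)
    data.frame(component = cc, icc = ic$icc, icc_lo = ic$ci_lo,
               icc_hi = ic$ci_hi, mad = mean(d), sd = sd(d),
               degenerate = isTRUE(ic$degenerate))
  }))
  pool <- function(which_comps) {
    m <- do.call(rbind, lapply(which_comps, function(cc)
      ratings[[cc]][keep, , drop = FALSE]))
    ic <- icc_safe(m)
    d <- between_diffs(m)
    data.frame(icc = ic$icc, icc_lo = ic$ci_lo, icc_hi = ic$ci_hi,
               mad = mean(d), sd = sd(d), degenerate = isTRUE(ic$degenerate))
  }
  ic_part <- icc_safe(part[keep, , drop = FALSE])
  summary <- rbind(
    cbind(data.frame(quantity = "part comparison registration"),
          data.frame(icc = ic_part$icc, icc_lo = ic_part$ci_lo,
                     icc_hi = ic_part$ci_hi,
                     mad = mean(part_between[keep]),
                     sd = sd(part_between[keep]),
                     degenerate = isTRUE(ic_part$degenerate))),
    cbind(data.frame(quantity = "translational changes (mm)"),
          pool(c("dMD", "dPF", "dIA"))),
    cbind(data.frame(quantity = "rotational changes (deg)"),
          pool(c("pitch", "roll", "yaw"))))
  structure(list(summary = summary, per_component = per_comp,
                 ratings = ratings, part_ratings = part,
                 part_between_mad = part_between,
                 n_cases = sum(keep), n_runs = n_runs, failed = failed,
                 perturbation = perturbation, segmentation = segmentation,
                 icc_form = "ICC(2,1) two-way random, absolute agreement",
                 note = "no multiple-testing correction applied"),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Simulated reliability study: %d cases x %d runs (%s segmentation)\n",
              x$n_cases, x$n_runs, x$segmentation))
  cat(x$icc_form, "\n")
  df <- x$summary
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 4)
  print(df, row.names = FALSE)
  if (length(x$failed))
    cat(sprintf("%d voided case-runs (see $failed)\n", length(x$failed)))
  invisible(x)
}
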