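#' Tissue class pool parameters
#'
#' A tissue class is a label plus the five-pool Lorentzian parameters of its
#' noise-free Z-spectrum. Amplitudes must lie in `[0, 1]` and their sum is
#' sanity-checked below 1.2 so the simulated Z-spectrum stays plausible.
#'
#' @param label Class label.
#' @param ds,mt,amide,amine,noe [lorentzian_line()] objects for the direct
#'   water saturation, semisolid MT, amide (+3.5 ppm), amine (+2.0 ppm) and
#'   NOE (-3.5 ppm) pools.
#' @param baseline Constant `c` of the forward model.
#' @return An object of class `tissue_class`.
#' @export
tissue_class <- function(label, ds, mt, amide, amine, noe, baseline = 1) {
  pools <- list(water = ds, mt = mt, amide = amide, amine = amine, noe = noe)
  for (p in pools) stopifnot(inherits(p, "lorentzian_line"))
  amps <- vapply(pools, `[[`, numeric(1), "amplitude")
  if (any(amps < 0 | amps > 1)) stop("pool amplitudes must lie in [0, 1]")
  if (sum(amps) >= 1.2) stop("sum of pool amplitudes must stay below 1.2")
  structure(c(list(label = label, c = baseline), pools),
            class = "tissue_class")
}

#' Default tissue classes
#'
#' Tumor / edema / normal-appearing tissue with pool amplitudes chosen so
#' the derived metrics land in literature-typical 3 T ranges (DS ~0.78-0.82,
#' MT ~0.10-0.17, amide ~0.04-0.06). These defaults are conveniences for the
#' simulator, not claims about any cohort.
#'
#' @return Named list of [tissue_class()] objects.
#' @export
default_tissue_classes <- function() {
  list(
    tumor = tissue_class(
      "tumor",
      ds    = lorentzian_line(0.80, 2.3, 0),
      mt    = lorentzian_line(0.14, 40, -1),
      amide = lorentzian_line(0.060, 1.1, 3.5),
      amine = lorentzian_line(0.025, 1.8, 2.0),
      noe   = lorentzian_line(0.055, 2.5, -3.5)
    ),
    edema = tissue_class(
      "edema",
      ds    = lorentzian_line(0.82, 2.1, 0),
      mt    = lorentzian_line(0.10, 40, -1),
      amide = lorentzian_line(0.045, 1.1, 3.5),
      amine = lorentzian_line(0.020, 1.8, 2.0),
      noe   = lorentzian_line(0.050, 2.5, -3.5)
    ),
    normal = tissue_class(
      "normal",
      ds    = lorentzian_line(0.78, 2.2, 0),
      mt    = lorentzian_line(0.17, 40, -1),
      amide = lorentzian_line(0.040, 1.1, 3.5),
      amine = lorentzian_line(0.020, 1.8, 2.0),
      noe   = lorentzian_line(0.065, 2.5, -3.5)
    )
  )
}

#' Phantom configuration
#'
#' Describes a synthetic single-slice acquisition: grid, tissue geometry,
#' a smooth second-order polynomial B0 field, optional per-frame in-plane
#' motion, and the noise model on the magnitude images.
#'
#' @param grid_shape Integer `(nx, ny)`.
#' @param tissue_classes Named list of [tissue_class()] objects containing at
#'   least `tumor`, `edema`, `normal`.
#' @param b0_coefficients Length-6 polynomial coefficients
#'   `(1, u, v, uv, u^2, v^2)` over unit coordinates `u, v` in `[-1, 1]`;
#'   the default yields peak shifts of roughly +/-0.4 ppm, a typical 3 T
#'   shim scale.
#' @param motion_shifts_px Optional `frames x 2` matrix of per-frame
#'   translations in pixels (`NULL` = no motion).
#' @param noise_sd Noise standard deviation as a fraction of S0.
#' @param noise_model `"gaussian"` (high-SNR magnitude default) or
#'   `"rician"`.
#' @param amplitude_jitter Relative (log-normal) per-voxel scatter of the
#'   pool amplitudes within a tissue class; gives the phantom within-class
#'   heterogeneity and randomizes voxels for recovery experiments.
#' @param schedule Acquisition [offset_schedule()].
#' @param s0_level Mean S0 signal level inside the brain (arbitrary units).
#' @param seed Integer seed making the phantom reproducible.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32, 32),
                           tissue_classes = default_tissue_classes(),
                           b0_coefficients = c(0.05, 0.10, -0.08, 0.06, 0.12, -0.10),
                           motion_shifts_px = NULL,
                           noise_sd = 0.005,
                           noise_model = c("gaussian", "rician"),
                           amplitude_jitter = 0.10,
                           schedule = build_default_offset_schedule(),
                           s0_level = 1000,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 8),
            length(b0_coefficients) == 6L, all(is.finite(b0_coefficients)),
            is.finite(noise_sd), noise_sd >= 0,
            is.finite(amplitude_jitter), amplitude_jitter >= 0)
  needed <- c("tumor", "edema", "normal")
  if (!all(needed %in% names(tissue_classes))) {
    stop("tissue_classes must contain 'tumor', 'edema' and 'normal'")
  }
  if (!is.null(motion_shifts_px)) {
    motion_shifts_px <- as.matrix(motion_shifts_px)
    stopifnot(ncol(motion_shifts_px) == 2L)
  }
  structure(
    list(grid_shape = as.integer(grid_shape), tissue_classes = tissue_classes,
         b0_coefficients = b0_coefficients, motion_shifts_px = motion_shifts_px,
         noise_sd = noise_sd, noise_model = noise_model,
         amplitude_jitter = amplitude_jitter, schedule = schedule,
         s0_level = s0_level, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# class geometry: elliptical brain, circular tumor, surrounding edema ring
phantom_geometry <- function(nx, ny) {
  u <- matrix(rep(seq(-1, 1, length.out = nx), ny), nx, ny)
  v <- matrix(rep(seq(-1, 1, length.out = ny), each = nx), nx, ny)
  brain <- (u / 0.92)^2 + (v / 0.85)^2 <= 1
  r_tum <- sqrt((u + 0.35)^2 + (v - 0.1)^2)
  tumor <- brain & r_tum <= 0.28
  edema <- brain & !tumor & r_tum <= 0.48
  normal <- brain & !tumor & !edema
  list(u = u, v = v, brain = brain, tumor = tumor, edema = edema,
       normal = normal)
}

#' Generate a synthetic CEST phantom
#'
#' Simulates the saturated-image stack (including the +300 ppm reference
#' frame), the S0 image, tissue masks, and ground-truth maps: per-voxel pool
#' amplitudes, the B0 field, and the noise-free MTR asymmetries at 3.5 and
#' 3.0 ppm. Reproducible given the config seed; the global RNG state is left
#' untouched.
#'
#' @param config A [phantom_config()].
#' @return An object of class `cest_phantom`: list with `saturated_stack`,
#'   `s0`, `schedule`, `masks` (logical matrices: `brain`, `tumor`, `edema`,
#'   `normal`), `truth` (amplitude maps `ds`, `mt`, `amide`, `amine`, `noe`;
#'   `b0_ppm`; `mtr35`; `mtrasym30`; per-voxel line parameter list
#'   `pool_params`), and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    nx <- config$grid_shape[1]; ny <- config$grid_shape[2]
    geo <- phantom_geometry(nx, ny)
    sched <- config$schedule
    offs_all <- sched$offsets_ppm
    n_frames <- length(offs_all)

    p <- config$b0_coefficients
    b0 <- p[1] + p[2] * geo$u + p[3] * geo$v + p[4] * geo$u * geo$v +
      p[5] * geo$u^2 + p[6] * geo$v^2
    b0[!geo$brain] <- 0

    s0 <- config$s0_level * (1 - 0.08 * (geo$u^2 + geo$v^2))
    s0[!geo$brain] <- 0

    pool_names <- c("ds", "mt", "amide", "amine", "noe")
    model_names <- c(ds = "water", mt = "mt", amide = "amide",
                     amine = "amine", noe = "noe")
    amp <- lapply(pool_names, function(p) matrix(NA_real_, nx, ny))
    names(amp) <- pool_names
    width <- center <- amp
    cvals <- matrix(NA_real_, nx, ny)

    for (cls in c("tumor", "edema", "normal")) {
      idx <- which(geo[[cls]])
      if (length(idx) == 0L) next
      tc <- config$tissue_classes[[cls]]
      cvals[idx] <- tc$c
      for (p in pool_names) {
        ln <- tc[[model_names[[p]]]]
        jit <- if (config$amplitude_jitter > 0) {
          exp(stats::rnorm(length(idx), 0, config$amplitude_jitter))
        } else rep(1, length(idx))
        amp[[p]][idx] <- pmin(ln$amplitude * jit, 1)
        width[[p]][idx] <- ln$fwhm
        center[[p]][idx] <- ln$center
      }
    }

    # noise-free Z for each brain voxel at all frames (vectorized per pool)
    idx <- which(geo$brain)
    zmat <- matrix(NA_real_, length(idx), n_frames)
    dw <- outer(rep(1, length(idx)), offs_all) - b0[idx]  # voxel x frame
    zmat[] <- cvals[idx]
    for (p in pool_names) {
      q <- (width[[p]][idx]^2) / 4
      zmat <- zmat - amp[[p]][idx] * q / (q + (dw - center[[p]][idx])^2)
    }

    # noise-free asymmetries on the B0-free spectrum (truth, not measurement)
    asym_truth <- function(ppm) {
      lor_at <- function(x) {
        out <- 0
        for (p in pool_names) {
          q <- (width[[p]][idx]^2) / 4
          out <- out + amp[[p]][idx] * q / (q + (x - center[[p]][idx])^2)
        }
        out
      }
      (lor_at(ppm) - lor_at(-ppm))  # Z(-x) - Z(x) = L(+x) - L(-x)
    }
    mtr35 <- mtrasym30 <- matrix(NA_real_, nx, ny)
    mtr35[idx] <- asym_truth(3.5)
    mtrasym30[idx] <- asym_truth(3.0)

    stack <- array(0, dim = c(nx, ny, n_frames))
    for (f in seq_len(n_frames)) {
      frame <- matrix(0, nx, ny)
      frame[idx] <- zmat[, f] * s0[idx]
      if (!is.null(config$motion_shifts_px)) {
        sh <- config$motion_shifts_px[((f - 1L) %% nrow(config$motion_shifts_px)) + 1L, ]
        frame <- fourier_shift(frame, sh[1], sh[2])
      }
      stack[, , f] <- frame
    }
    if (config$noise_sd > 0) {
      sd_abs <- config$noise_sd * config$s0_level
      if (config$noise_model == "gaussian") {
        stack <- stack + array(stats::rnorm(length(stack), 0, sd_abs), dim(stack))
      } else {
        n1 <- array(stats::rnorm(length(stack), 0, sd_abs), dim(stack))
        n2 <- array(stats::rnorm(length(stack), 0, sd_abs), dim(stack))
        stack <- sqrt((stack + n1)^2 + n2^2)
      }
    }

    structure(
      list(saturated_stack = stack, s0 = s0, schedule = sched,
           masks = list(brain = geo$brain, tumor = geo$tumor,
                        edema = geo$edema, normal = geo$normal),
           truth = list(ds = amp$ds, mt = amp$mt, amide = amp$amide,
                        amine = amp$amine, noe = amp$noe, b0_ppm = b0,
                        mtr35 = mtr35, mtrasym30 = mtrasym30,
                        pool_params = list(amplitude = amp, fwhm = width,
                                           center = center, c = cvals)),
           config = config),
      class = "cest_phantom"
    )
  })
}

#' Cohort configuration
#'
#' Describes a two-group synthetic cohort: group sizes, per-pool group
#' effects applied to the second group's tumor tissue, and a log-normal
#' between-subject random effect on every pool amplitude.
#'
#' @param n_per_group Length-2 integer vector, each `>= 2`.
#' @param group_labels Length-2 character vector.
#' @param group_effects Named list of effects on tumor pool amplitudes for
#'   the second group, e.g.
#'   `list(amide = list(type = "multiplicative", value = 1.3))`; types are
#'   `"multiplicative"` or `"additive"`.
#' @param between_subject_sd Log-scale SD of the per-subject amplitude
#'   multiplier.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(12, 12),
                          group_labels = c("A", "B"),
                          group_effects = list(),
                          between_subject_sd = 0.10,
                          seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 2),
            length(group_labels) == 2L,
            is.finite(between_subject_sd), between_subject_sd >= 0)
  for (eff in group_effects) {
    stopifnot(eff$type %in% c("multiplicative", "additive"),
              is.finite(eff$value))
  }
  structure(
    list(n_per_group = as.integer(n_per_group), group_labels = group_labels,
         group_effects = group_effects,
         between_subject_sd = between_subject_sd, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# apply subject multiplier and (group 2 only) configured effects to the
# tumor tissue class of a phantom config
.subject_phantom_config <- function(phantom_cfg, subject_mult, effects,
                                    apply_effects, subject_seed) {
  tc <- phantom_cfg$tissue_classes
  tum <- tc$tumor
  for (p in c("water", "mt", "amide", "amine", "noe")) {
    key <- c(water = "ds", mt = "mt", amide = "amide", amine = "amine",
             noe = "noe")[[p]]
    a <- tum[[p]]$amplitude * subject_mult[[key]]
    if (apply_effects && !is.null(effects[[key]])) {
      eff <- effects[[key]]
      a <- if (eff$type == "multiplicative") a * eff$value else a + eff$value
    }
    tum[[p]] <- lorentzian_line(min(max(a, 0), 1), tum[[p]]$fwhm,
                                tum[[p]]$center, tum[[p]]$plateau_bw)
  }
  tc$tumor <- tum
  phantom_config(grid_shape = phantom_cfg$grid_shape, tissue_classes = tc,
                 b0_coefficients = phantom_cfg$b0_coefficients,
                 motion_shifts_px = phantom_cfg$motion_shifts_px,
                 noise_sd = phantom_cfg$noise_sd,
                 noise_model = phantom_cfg$noise_model,
                 amplitude_jitter = phantom_cfg$amplitude_jitter,
                 schedule = phantom_cfg$schedule,
                 s0_level = phantom_cfg$s0_level, seed = subject_seed)
}

#' Generate a synthetic two-group cohort
#'
#' In `"features"` mode each subject is reduced to its ground-truth tumor
#' histogram features (fast; used for statistical calibration experiments):
#' per-voxel tumor pool amplitudes are drawn with the configured jitter and
#' subject-level multiplier, and summarized with
#' [extract_histogram_features()]. In `"images"` mode a full
#' [generate_phantom()] dataset is returned per subject for end-to-end runs.
#'
#' @param config A [cohort_config()].
#' @param phantom A [phantom_config()] serving as the subject template.
#' @param mode `"features"` or `"images"`.
#' @return A list with `labels` (factor of group labels) and either
#'   `features` (data.frame: subject, group, metric, mean, median, p10, p25,
#'   p75, p90, n_voxels) or `subjects` (list of `cest_phantom`).
#' @export
generate_cohort <- function(config, phantom = phantom_config(),
                            mode = c("features", "images")) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(phantom, "phantom_config"))
  mode <- match.arg(mode)
  n_tot <- sum(config$n_per_group)
  group <- rep(config$group_labels, config$n_per_group)
  pool_names <- c("ds", "mt", "amide", "amine", "noe")

  with_seed(config$seed, {
    subject_seeds <- sample.int(2^31 - 2, n_tot)
    mults <- replicate(n_tot, {
      m <- exp(stats::rnorm(length(pool_names), 0, config$between_subject_sd))
      names(m) <- pool_names
      m
    }, simplify = FALSE)

    if (mode == "images") {
      subjects <- vector("list", n_tot)
      for (i in seq_len(n_tot)) {
        cfg_i <- .subject_phantom_config(phantom, mults[[i]],
                                         config$group_effects,
                                         group[i] == config$group_labels[2],
                                         subject_seeds[i])
        subjects[[i]] <- generate_phantom(cfg_i)
      }
      return(list(labels = factor(group, levels = config$group_labels),
                  subjects = subjects))
    }

    geo <- phantom_geometry(phantom$grid_shape[1], phantom$grid_shape[2])
    n_vox <- sum(geo$tumor)
    rows <- vector("list", n_tot)
    for (i in seq_len(n_tot)) {
      cfg_i <- .subject_phantom_config(phantom, mults[[i]],
                                       config$group_effects,
                                       group[i] == config$group_labels[2],
                                       subject_seeds[i])
      tum <- cfg_i$tissue_classes$tumor
      per_metric <- lapply(pool_names, function(p) {
        nm <- c(ds = "water", mt = "mt", amide = "amide", amine = "amine",
                noe = "noe")[[p]]
        base <- tum[[nm]]$amplitude
        jit <- if (phantom$amplitude_jitter > 0) {
          exp(stats::rnorm(n_vox, 0, phantom$amplitude_jitter))
        } else rep(1, n_vox)
        pmin(base * jit, 1)
      })
      names(per_metric) <- pool_names
      rows[[i]] <- do.call(rbind, lapply(pool_names, function(p) {
        f <- extract_histogram_features(matrix(per_metric[[p]], ncol = 1),
                                        roi_mask("tumor", matrix(TRUE, n_vox, 1)),
                                        metric = p, min_voxels = 2)
        cbind(data.frame(subject = sprintf("S%03d", i), group = group[i],
                         stringsAsFactors = FALSE), f)
      }))
    }
    list(labels = factor(group, levels = config$group_labels),
         features = do.call(rbind, rows))
  })
}
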