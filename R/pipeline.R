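#' Pipeline configuration
#'
#' Assembles the configuration of [run_pipeline()] with the study defaults:
#' three tissue groups, three samples per group, four slices per sample
#' (one ROI per slice, so n = 12 observations per group), the high multi
#' b-value protocol for directional modelling and the high angular
#' resolution protocol for DKI, and Rician noise at SNR 20.
#'
#' @param groups tissue groups to simulate.
#' @param n_samples samples per group.
#' @param n_slices slices per sample (= ROIs per sample).
#' @param grid_xy in-plane grid size (voxels).
#' @param ring_inner,ring_outer media annulus radii (voxels).
#' @param snr_b0 signal-to-noise ratio at b = 0 (`Inf` disables noise).
#' @param models model stages to run; any of `"dti"`, `"stretched"`,
#'   `"kurtosis"`, `"biexp"` (all on the HMb protocol) and `"dki"`
#'   (HAR protocol, which also adds the HAR DTI/Westin indices).
#' @param denoise run MP-PCA noise estimation and Rician bias correction.
#' @param patch_radius MP-PCA patch radius.
#' @param max_voxels_per_slice cap on media voxels per slice entering the
#'   per-voxel non-Gaussian fits (seeded subsample; directional fitting is
#'   the expensive stage). `Inf` fits every voxel.
#' @param out_dir optional output directory for maps, tables and manifest.
#' @param seed top-level seed; all stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(groups = c("native", "collagenase",
                                       "decellularized"),
                            n_samples = 3, n_slices = 4,
                            grid_xy = 24, ring_inner = 4, ring_outer = 8,
                            snr_b0 = 20,
                            models = c("dti", "stretched", "kurtosis",
                                       "biexp", "dki"),
                            denoise = TRUE, patch_radius = 1,
                            max_voxels_per_slice = 30,
                            out_dir = NULL, seed = 1L) {
  structure(
    list(groups = groups, n_samples = n_samples, n_slices = n_slices,
         grid_xy = grid_xy, ring_inner = ring_inner,
         ring_outer = ring_outer, snr_b0 = snr_b0, models = models,
         denoise = denoise, patch_radius = patch_radius,
         max_voxels_per_slice = max_voxels_per_slice,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# Summarise per-voxel values (tibble with k = slice, value) into slice-level
# ROI rows.
summarise_by_slice <- function(tb, group, sample_id, index_name) {
  tb |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     n_voxels = dplyr::n(), .groups = "drop") |>
    dplyr::transmute(group = group, sample_id = sample_id,
                     slice_id = .data$k, index_name = index_name,
                     mean = .data$mean, sd = .data$sd,
                     n_voxels = .data$n_voxels)
}

process_sample <- function(config, group, sample_idx, scheme_hmb, scheme_har) {
  spec <- phantom_spec(
    phenotype = group,
    grid_shape = c(config$grid_xy, config$grid_xy, config$n_slices),
    ring_inner = config$ring_inner, ring_outer = config$ring_outer,
    snr_b0 = config$snr_b0,
    seed = child_seed(config$seed,
                      10 * match(group, config$groups) + sample_idx)
  )
  phantom <- make_phantom(spec, scheme_hmb)
  volume <- phantom$volume
  floor_raw <- noise_floor(volume, phantom$background_mask)
  if (config$denoise && is.finite(config$snr_b0)) {
    est <- mppca_denoise(volume, patch_radius = config$patch_radius)
    volume <- rician_bias_correct(
      dwi_volume(est$denoised, volume$scheme, volume$voxel_size), est
    )
  }

  summaries <- list()
  sample_id <- paste0(substr(group, 1, 1), sample_idx)

  tf <- fit_dti(volume, bmax = 900, mask = phantom$media_mask)
  fa <- fa_md(cbind(tf$l1, tf$l2, tf$l3))
  dti_tb <- dplyr::bind_cols(tf[, c("i", "j", "k", "clipped")], fa,
                             Dv1 = tf$l1, Dv2 = tf$l2, Dv3 = tf$l3)
  dti_tb <- dti_tb[!dti_tb$clipped, ]
  for (idx in c("FA", "MD", "Dv1", "Dv2", "Dv3")) {
    summaries[[length(summaries) + 1]] <- summarise_by_slice(
      tibble::tibble(k = dti_tb$k, value = dti_tb[[idx]]),
      group, sample_id, idx
    )
  }

  directional <- intersect(config$models, c("stretched", "kurtosis", "biexp"))
  if (length(directional) > 0) {
    sub <- tf[!tf$clipped, ]
    sub <- dplyr::group_by(sub, .data$k)
    sub <- with_seed(child_seed(config$seed, 77 + sample_idx), {
      dplyr::slice_sample(sub,
                          n = min(config$max_voxels_per_slice, 10000L))
    })
    sub <- dplyr::ungroup(sub)
    dir_rows <- vector("list", nrow(sub) * 3L)
    n_found <- 0L
    for (r in seq_len(nrow(sub))) {
      row <- sub[r, ]
      for (w in 1:3) {
        decay <- tryCatch(extract_directional_decay(volume, row, w),
                          error = function(e) NULL)
        if (is.null(decay)) next
        vals <- list()
        if ("stretched" %in% directional) {
          st <- fit_stretched(decay)
          vals[[length(vals) + 1]] <- tibble::tibble(
            index_name = paste0(c("Dst_v", "alpha_v"), w),
            value = c(st$D_st, st$alpha)
          )
        }
        if ("kurtosis" %in% directional) {
          ku <- fit_kurtosis_1d(decay)
          vals[[length(vals) + 1]] <- tibble::tibble(
            index_name = paste0(c("Dk_v", "K_v"), w),
            value = c(ku$D_app, ku$K_app)
          )
        }
        if ("biexp" %in% directional) {
          be <- fit_biexp(decay)
          vals[[length(vals) + 1]] <- tibble::tibble(
            index_name = paste0(c("Df_v", "Ds_v"), w),
            value = c(be$D_f, be$D_s)
          )
        }
        n_found <- n_found + 1L
        dir_rows[[n_found]] <- dplyr::bind_rows(vals) |>
          dplyr::mutate(k = row$k)
      }
    }
    dir_tb <- dplyr::bind_rows(dir_rows[seq_len(n_found)])
    for (idx in unique(dir_tb$index_name)) {
      summaries[[length(summaries) + 1]] <- summarise_by_slice(
        dir_tb[dir_tb$index_name == idx, c("k", "value")],
        group, sample_id, idx
      )
    }
  }

  maps <- list(
    FA = map_from_tibble(dti_tb, "FA", dim(phantom$media_mask)),
    MD = map_from_tibble(dti_tb, "MD", dim(phantom$media_mask))
  )

  if ("dki" %in% config$models) {
    spec_har <- spec
    spec_har$seed <- child_seed(config$seed,
                                500 + 10 * match(group, config$groups) +
                                  sample_idx)
    ph_har <- make_phantom(spec_har, scheme_har)
    vol_har <- ph_har$volume
    if (config$denoise && is.finite(config$snr_b0)) {
      est <- mppca_denoise(vol_har, patch_radius = config$patch_radius)
      vol_har <- rician_bias_correct(
        dwi_volume(est$denoised, vol_har$scheme, vol_har$voxel_size), est
      )
    }
    tf_har <- fit_dti(vol_har, bmax = 800, mask = ph_har$media_mask,
                      refine = FALSE)
    tf_har <- tf_har[!tf_har$clipped, ]
    fa_har <- fa_md(cbind(tf_har$l1, tf_har$l2, tf_har$l3))
    ws <- westin_shapes(cbind(tf_har$l1, tf_har$l2, tf_har$l3))
    har_tb <- dplyr::bind_cols(tf_har[, c("i", "j", "k")], fa_har, ws)
    for (idx in c("FA", "MD", "C_L", "C_P", "C_S")) {
      nm <- if (idx %in% c("FA", "MD")) paste0(idx, "_har") else idx
      summaries[[length(summaries) + 1]] <- summarise_by_slice(
        tibble::tibble(k = har_tb$k, value = har_tb[[idx]]),
        group, sample_id, nm
      )
    }
    dk <- fit_dki_tensor(vol_har, mask = ph_har$media_mask)
    dk_sub <- dplyr::group_by(dk, .data$k)
    dk_sub <- with_seed(child_seed(config$seed, 600 + sample_idx), {
      dplyr::slice_sample(dk_sub,
                          n = min(config$max_voxels_per_slice, 10000L))
    })
    dk_sub <- dplyr::ungroup(dk_sub)
    dki_rows <- purrr::map(seq_len(nrow(dk_sub)), function(r) {
      ind <- tryCatch(dki_indices(dk_sub[r, ]), error = function(e) NULL)
      if (is.null(ind)) return(NULL)
      dplyr::mutate(ind, k = dk_sub$k[r])
    })
    dki_tb <- dplyr::bind_rows(dki_rows)
    for (idx in c("KA", "MK", "AK", "RK", "TORT")) {
      summaries[[length(summaries) + 1]] <- summarise_by_slice(
        tibble::tibble(k = dki_tb$k, value = dki_tb[[idx]]),
        group, sample_id, idx
      )
    }
  }

  list(
    summaries = dplyr::bind_rows(summaries),
    noise_floor = tibble::tibble(group = group, sample_id = sample_id,
                                 noise_floor = floor_raw),
    maps = maps
  )
}

map_from_tibble <- function(tb, col, dims) {
  m <- array(NA_real_, dims)
  m[cbind(tb$i, tb$j, tb$k)] <- tb[[col]]
  m
}

#' Run the full phantom-to-report pipeline
#'
#' Simulates arterial-ring phantoms for each group and sample, estimates
#' and removes noise, fits the diffusion tensor (b <= 900 s/mm^2 on the
#' high multi b-value protocol), extracts decays along the tensor
#' eigenvectors and fits the stretched-exponential, kurtosis and
#' bi-exponential models, fits the kurtosis tensor on the high angular
#' resolution protocol (DTI comparator at b <= 800 s/mm^2), derives all
#' scalar indices, aggregates them into slice-level ROI summaries and
#' compares groups by one-way ANOVA with Tukey post-hoc tests. The whole
#' run is deterministic given the seed in the configuration.
#'
#' @param config a [pipeline_config()].
#' @return A `microstructure_report`: a list with `roi_summaries`,
#'   `comparisons` (one ANOVA row per index), `posthoc` (pairwise rows),
#'   `noise_floor`, `config`, `maps` (per-sample FA/MD arrays). If
#'   `config$out_dir` is set, TSV tables, NIfTI maps and a JSON run
#'   manifest are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  scheme_hmb <- build_hmb_scheme(seed = child_seed(config$seed, 1))
  scheme_har <- if ("dki" %in% config$models) {
    build_har_scheme(seed = child_seed(config$seed, 2))
  } else NULL

  all_summaries <- list()
  floors <- list()
  maps <- list()
  for (group in config$groups) {
    for (s in seq_len(config$n_samples)) {
      res <- tryCatch(
        process_sample(config, group, s, scheme_hmb, scheme_har),
        error = function(e) {
          abort(sprintf("pipeline stage failed for %s sample %d: %s",
                        group, s, conditionMessage(e)))
        }
      )
      all_summaries[[length(all_summaries) + 1]] <- res$summaries
      floors[[length(floors) + 1]] <- res$noise_floor
      maps[[paste0(group, "_", s)]] <- res$maps
    }
  }
  roi_summaries <- dplyr::bind_rows(all_summaries)
  floors <- dplyr::bind_rows(floors)

  comparisons <- list()
  posthoc <- list()
  if (length(config$groups) >= 2) {
    for (idx in unique(roi_summaries$index_name)) {
      d <- roi_summaries[roi_summaries$index_name == idx, ]
      cmp <- tryCatch(one_way_anova(d, index_name = idx),
                      error = function(e) NULL)
      if (is.null(cmp)) next
      comparisons[[length(comparisons) + 1]] <- generics::glance(cmp)
      posthoc[[length(posthoc) + 1]] <- generics::tidy(cmp)
    }
  }
  report <- structure(
    list(
      roi_summaries = roi_summaries,
      comparisons = dplyr::bind_rows(comparisons),
      posthoc = dplyr::bind_rows(posthoc),
      noise_floor = floors,
      maps = maps,
      config = config
    ),
    class = "microstructure_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.microstructure_report <- function(x, ...) {
  cat(sprintf(
    "<microstructure_report>  %d ROI summaries, %d indices, %d groups\n",
    nrow(x$roi_summaries), length(unique(x$roi_summaries$index_name)),
    length(unique(x$roi_summaries$group))
  ))
  if (nrow(x$comparisons) > 0) {
    cat("group comparisons (one-way ANOVA):\n")
    print(x$comparisons, n = Inf)
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_plain <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(out_dir, name),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_tsv_plain(report$roi_summaries, "roi_summaries.tsv")
  if (nrow(report$comparisons) > 0) {
    write_tsv_plain(report$comparisons, "anova.tsv")
    write_tsv_plain(report$posthoc, "posthoc.tsv")
  }
  write_tsv_plain(report$noise_floor, "noise_floor.tsv")
  for (nm in names(report$maps)) {
    for (map_nm in names(report$maps[[nm]])) {
      write_map_nifti(report$maps[[nm]][[map_nm]],
                      file.path(out_dir, paste0(nm, "_", map_nm, ".nii.gz")))
    }
  }
  manifest <- list(
    package = "arterydmri",
    version = as.character(utils::packageVersion("arterydmri")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = report$config$seed,
    config = report$config[setdiff(names(report$config), "out_dir")]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a phantom to disk
#'
#' Emits the 4-D volume as NIfTI with FSL bval/bvec gradient tables, the
#' media and background masks as NIfTI, and a YAML sidecar recording the
#' phantom specification and seed.
#'
#' @param phantom result of [make_phantom()].
#' @param dir output directory.
#' @param name file-name stem.
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(ext) file.path(dir, paste0(name, ext))
  write_dwi(phantom$volume, p(".nii.gz"), p(".bval"), p(".bvec"))
  vx <- phantom$volume$voxel_size
  write_map_nifti(phantom$media_mask * 1, p("_media_mask.nii.gz"), vx)
  write_map_nifti(phantom$background_mask * 1, p("_background_mask.nii.gz"), vx)
  spec <- phantom$spec
  yaml::write_yaml(list(
    phenotype = spec$phenotype, grid_shape = spec$grid_shape,
    ring_inner = spec$ring_inner, ring_outer = spec$ring_outer,
    snr_b0 = if (is.finite(spec$snr_b0)) spec$snr_b0 else "Inf",
    seed = spec$seed, s0 = spec$s0,
    v_f = spec$compartments$v_f,
    D_f_eigs = spec$compartments$D_f_eigs,
    D_s_eigs = spec$compartments$D_s_eigs
  ), p("_spec.yaml"))
  invisible(dir)
}
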