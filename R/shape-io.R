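# CSV / JSON interchange for rib curve populations and shape models.

#' Write / read rib-curve populations as CSV
#'
#' Curve file columns: `subject_id`, `rib_level`, `side`, `point_index`,
#' `x_mm`, `y_mm`, `z_mm`. Metadata file columns: `subject_id`, `age_years`,
#' `height_m`, `weight_kg`. The two functions round-trip.
#'
#' @param population List of [ribcage_geometry()] objects.
#' @param path Curve CSV path.
#' @param meta_path Optional metadata CSV path.
#' @return `read_rib_curves_csv()` returns a list of
#'   [ribcage_geometry()]; the writer returns `path` invisibly.
#' @export
write_rib_curves_csv <- function(population, path, meta_path = NULL) {
  rows <- lapply(seq_along(population), function(j) {
    rc <- population[[j]]
    do.call(rbind, lapply(rc$curves, function(cv) {
      data.frame(subject_id = j, rib_level = cv$rib_level, side = cv$side,
                 point_index = seq_len(nrow(cv$points)),
                 x_mm = cv$points[, 1], y_mm = cv$points[, 2],
                 z_mm = cv$points[, 3])
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- do.call(rbind, lapply(seq_along(population), function(j) {
      m <- population[[j]]$meta
      data.frame(subject_id = j,
                 age_years = m$age %||% NA_real_,
                 height_m = m$height %||% NA_real_,
                 weight_kg = m$weight %||% NA_real_)
    }))
    write.csv(meta, meta_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_rib_curves_csv
#' @export
read_rib_curves_csv <- function(path, meta_path = NULL) {
  df <- read.csv(path)
  meta <- if (!is.null(meta_path)) read.csv(meta_path) else NULL
  lapply(split(df, df$subject_id), function(sub) {
    curves <- lapply(split(sub, paste(sub$rib_level, sub$side)), function(cv) {
      cv <- cv[order(cv$point_index), ]
      rib_curve(cv$rib_level[1], cv$side[1],
                cbind(cv$x_mm, cv$y_mm, cv$z_mm))
    })
    m <- NULL
    if (!is.null(meta)) {
      row <- meta[meta$subject_id == sub$subject_id[1], ]
      if (nrow(row) == 1) {
        m <- list(age = row$age_years, height = row$height_m,
                  weight = row$weight_kg)
      }
    }
    ribcage_geometry(unname(curves), m)
  })
}

#' Archive / restore a fitted shape model
#'
#' Writes a JSON header (k, score SDs, explained variance, point count) plus
#' CSV matrices for the mean vector and the components under `dir`.
#'
#' @param model A `"shape_model"`.
#' @param dir Directory (created if needed).
#' @return `read_shape_model()` returns the restored `"shape_model"`.
#' @export
write_shape_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- list(k = model$k, sigma = model$sigma,
                 explained_variance = model$explained_variance,
                 npts = model$npts, n_train = model$n_train,
                 rank = model$rank)
  jsonlite::write_json(header, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(mu = model$mu), file.path(dir, "mu.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(t(model$components)),
            file.path(dir, "components.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "model.json"),
                                simplifyVector = TRUE)
  mu <- read.csv(file.path(dir, "mu.csv"))$mu
  comps <- t(as.matrix(read.csv(file.path(dir, "components.csv"))))
  structure(list(mu = mu, components = unname(comps),
                 sigma = header$sigma,
                 explained_variance = header$explained_variance,
                 npts = header$npts, k = header$k,
                 n_train = header$n_train, rank = header$rank),
            class = "shape_model")
}

#' Export morph-target rib curves for one (component, s) setting
#'
#' Writes the discretized target curves produced by [generate_ribcage()] as
#' a point-set CSV (no mesh morphing is performed).
#'
#' @param model A `"shape_model"`.
#' @param i Component index.
#' @param s Scaling coordinate.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_morph_target <- function(model, i, s, path) {
  rc <- generate_ribcage(model, i, s)
  write_rib_curves_csv(list(rc), path)
}
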