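#' Read a feature table from CSV
#'
#' The interchange schema is a comma-delimited UTF-8 file with header
#' `class,instance,f1,...,fL`: one row per training instance, numeric
#' feature fields, instance indices unique within class.  The
#' `instance` bookkeeping column is validated and dropped, so the
#' returned tibble (a `class` column plus numeric features) feeds
#' directly into [iatr_train()] and friends.
#'
#' @param path file path.
#' @return tibble with `class` and feature columns, instance order
#'   preserved.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0L) {
    abort(sprintf("malformed CSV at line %d: %s", prob$row[1L] + 1L,
                  prob$expected[1L]))
  }
  if (!all(c("class", "instance") %in% names(df))) {
    abort("schema error: header must contain 'class' and 'instance'")
  }
  feats <- setdiff(names(df), c("class", "instance"))
  if (length(feats) == 0L) abort("schema error: no feature columns")
  for (f in feats) {
    if (!is.numeric(df[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[f]]))))[1L]
      abort(sprintf("non-numeric value in column '%s' at line %d",
                    f, bad + 1L))
    }
  }
  dup <- df |>
    dplyr::count(.data$class, .data$instance) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate instance index %s within class '%s'",
                  dup$instance[1L], dup$class[1L]))
  }
  df$class <- as.character(df$class)
  df[c("class", feats)]
}

#' Write a feature table to CSV
#'
#' Writes the interchange schema of [read_feature_csv()], inserting the
#' per-class `instance` index column.  Values are written with full
#' round-trippable precision.
#'
#' @param data tibble with a `class` column and numeric features.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(data, path) {
  mats <- split_classes(data, "class")   # validates invariants
  out <- tibble::as_tibble(data)
  out$class <- as.character(out$class)
  out <- dplyr::mutate(dplyr::group_by(out, .data$class),
                       instance = dplyr::row_number(), .after = "class")
  out <- dplyr::ungroup(out)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Persist intermediate templates
#'
#' Writes the per-class template matrices as CSV (columns
#' `class,template_index,f1..fL`) with a JSON sidecar
#' (`<path>.json`) recording the configuration and the element-wise
#' provenance (the original instance index behind every template
#' element).
#'
#' @param templates an [iatr_train()] result.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path) {
  stopifnot(inherits(templates, "iatr_templates"))
  long <- dplyr::bind_rows(purrr::imap(templates$templates, function(m, cl) {
    df <- tibble::as_tibble(as.data.frame(m))
    names(df) <- templates$feature_names %||% feature_names(ncol(m))
    dplyr::bind_cols(tibble::tibble(class = cl,
                                    template_index = seq_len(nrow(m))), df)
  }))
  readr::write_csv(long, path, progress = FALSE)
  cfg <- templates$config
  sidecar <- list(
    config = list(K = cfg$K, P = cfg$P, F = cfg$n_final,
                  S = cfg$n_query %||% cfg$n_final,
                  metric = if (is.function(cfg$metric)) "custom" else cfg$metric,
                  other_class_agg = cfg$other_class_agg),
    K_resolved = as.list(templates$K),
    sizes = as.list(templates$sizes),
    provenance = lapply(templates$provenance, unname))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read persisted templates
#'
#' Rebuilds an `iatr_templates` object from the CSV + JSON sidecar pair
#' written by [write_templates()] (bounds of the original training data
#' are not stored and are left `NULL`).
#'
#' @param path CSV path previously given to [write_templates()].
#' @return an `iatr_templates` object.
#' @export
read_templates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  feats <- setdiff(names(df), c("class", "template_index"))
  classes <- unique(df$class)
  tm <- lapply(classes, function(cl) {
    m <- as.matrix(df[df$class == cl, feats, drop = FALSE])
    rownames(m) <- NULL
    m
  })
  names(tm) <- classes
  cfg <- iatr_config(
    K = side$config$K, P = side$config$P, n_final = side$config$F,
    n_query = side$config$S, metric = "l1",
    other_class_agg = side$config$other_class_agg %||% "mean")
  structure(
    list(templates = tm,
         provenance = lapply(side$provenance, function(p) {
           storage.mode(p) <- "integer"
           p
         }),
         bounds = NULL,
         sizes = unlist(side$sizes),
         K = vapply(tm, nrow, integer(1)),
         feature_names = feats,
         config = cfg),
    class = "iatr_templates")
}
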