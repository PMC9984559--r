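#' Variant manifests
#'
#' A manifest lists the variants of one gene: a data frame with columns
#' `variant_id`, `gene`, `class_label` (one of benign, pathogenic, unknown,
#' wt) and `data_path` (path to the variant's torsion table; may be NA when
#' trajectories are held in memory). Variant ids must be unique.
#'
#' @param variant_id,gene,class_label,data_path Column vectors.
#' @return A `data.frame` of class `variant_manifest`.
#' @export
variant_manifest <- function(variant_id, gene, class_label,
                             data_path = NA_character_) {
  ok <- c("benign", "pathogenic", "unknown", "wt")
  if (!all(class_label %in% ok))
    stop_dlrpmds("class_label must be one of: %s", paste(ok, collapse = ", "))
  if (anyDuplicated(variant_id))
    stop_dlrpmds("variant_id values must be unique")
  out <- data.frame(variant_id = as.character(variant_id),
                    gene = as.character(gene),
                    class_label = as.character(class_label),
                    data_path = as.character(data_path),
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_manifest", "data.frame")
  out
}

#' @rdname variant_manifest
#' @param path CSV file path.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "gene", "class_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_dlrpmds("manifest '%s' missing column(s): %s", path,
                 paste(miss, collapse = ", "))
  if (is.null(df$data_path)) df$data_path <- NA_character_
  variant_manifest(df$variant_id, df$gene, df$class_label, df$data_path)
}

#' @rdname variant_manifest
#' @param manifest A `variant_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}
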