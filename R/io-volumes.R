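#' Read and write scalar volumes as NIfTI
#'
#' Thin wrappers over RNifti keeping the (array, affine) pair the package
#' works with internally.
#'
#' @param data 3-D or 4-D numeric array.
#' @param affine 4 x 4 voxel-to-world (RAS mm) matrix.
#' @param file Path, `.nii` or `.nii.gz`.
#' @return `write_nifti_volume()` returns `file` invisibly;
#'   `read_nifti_volume()` a list with `data` and `affine`.
#' @export
write_nifti_volume <- function(data, affine, file) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(file) {
  img <- RNifti::readNifti(file)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Write fitted metric maps to a directory
#'
#' One scalar NIfTI per metric (`FW, FA, MD, AD, RD`) plus an integer
#' `n_aniso` compartment-count map.
#'
#' @param fitted Result of [fit_volume()].
#' @param affine Grid affine.
#' @param dir Output directory (created).
#' @return Named vector of written paths, invisibly.
#' @export
write_metric_maps <- function(fitted, affine, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (m in names(fitted$metrics)) {
    f <- file.path(dir, paste0(m, ".nii.gz"))
    write_nifti_volume(fitted$metrics[[m]], affine, f)
    paths[m] <- f
  }
  f <- file.path(dir, "n_aniso.nii.gz")
  nmap <- fitted$n_aniso
  storage.mode(nmap) <- "integer"
  write_nifti_volume(nmap, affine, f)
  paths["n_aniso"] <- f
  invisible(paths)
}

#' Read and write long-form profile tables
#'
#' The canonical exchange format is a long TSV with columns `subject,
#' bundle, metric, node, value` (plus any extra columns such as
#' `weight_sum`). `pivot_profiles_wide()` gives the human-readable wide
#' form, one column per node.
#'
#' @param profiles Long profile tibble.
#' @param file TSV path.
#' @return `read_profiles()` returns the tibble; writers return the input,
#'   invisibly.
#' @export
write_profiles <- function(profiles, file) {
  readr::write_tsv(profiles, file)
  invisible(profiles)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(file) {
  readr::read_tsv(file, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = readr::col_character(),
                    bundle = readr::col_character(),
                    metric = readr::col_character(),
                    node = readr::col_integer(),
                    value = readr::col_double(),
                    .default = readr::col_guess()
                  ))
}

#' @rdname write_profiles
#' @export
pivot_profiles_wide <- function(profiles) {
  tidyr::pivot_wider(
    profiles[, c("subject", "bundle", "metric", "node", "value")],
    names_from = "node", values_from = "value", names_prefix = "node_"
  )
}

#' Read and write subject metadata
#'
#' TSV with columns `subject, group, age, sex, center` and optional
#' clinical scores (`AES`, ...).
#'
#' @param meta Metadata tibble.
#' @param file TSV path.
#' @export
write_metadata <- function(meta, file) {
  readr::write_tsv(meta, file)
  invisible(meta)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(file) {
  meta <- readr::read_tsv(file, show_col_types = FALSE,
                          col_types = readr::cols(
                            subject = readr::col_character(),
                            .default = readr::col_guess()
                          ))
  need <- c("subject", "group")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("metadata TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$subject)) stop("duplicate subject ids", call. = FALSE)
  meta
}
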