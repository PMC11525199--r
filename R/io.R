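#' Read a clone table (TSV)
#'
#' Tab-separated clone records with header
#' `animal_id  condition  t_days  basal  suprabasal`. Counts must be
#' non-negative integers and chase times non-negative; violations are
#' reported with the offending row number.
#'
#' @param path file path.
#' @return Clone-record data.frame.
#' @export
read_clone_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "condition", "t_days", "basal", "suprabasal")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("clone table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("t_days", "basal", "suprabasal")) {
    v <- d[[col]]
    bad <- which(!is.finite(v) | v < 0 |
                   (col != "t_days" & v != as.integer(v)))
    if (length(bad))
      stop("invalid ", col, " at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d$basal <- as.integer(d$basal)
  d$suprabasal <- as.integer(d$suprabasal)
  d[need]
}

#' Write a clone table (TSV), optionally with a ground-truth sidecar
#'
#' @param records clone-record data.frame; a `truth` attribute, if present
#'   and `sidecar = TRUE`, is written next to the table as
#'   `<path>.truth.json`.
#' @param path output file path.
#' @param sidecar write the truth sidecar when available.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(records, path, sidecar = TRUE) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- attr(records, "truth")
  if (sidecar && !is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and cross-validate mutation and donor tables (TSV)
#'
#' The mutation table needs columns `donor_id`, `sample_id`, `gene`,
#' `aa_change`, `consequence`, `vaf`; the donor table needs `donor_id`,
#' `age`, `bmi` and either `area_cm2` or `n_samples` + `sample_area_mm2`.
#' Every clone's donor must exist and VAFs must lie in (0, 1]; offenders are
#' listed in the error.
#'
#' @param mutations_path,donors_path file paths.
#' @return List with `mutations` and `donors` data.frames.
#' @export
read_mutation_tables <- function(mutations_path, donors_path) {
  mut <- utils::read.delim(mutations_path, stringsAsFactors = FALSE)
  don <- utils::read.delim(donors_path, stringsAsFactors = FALSE)
  need_m <- c("donor_id", "sample_id", "gene", "aa_change", "consequence",
              "vaf")
  if (length(setdiff(need_m, names(mut))))
    stop("mutation table is missing column(s): ",
         paste(setdiff(need_m, names(mut)), collapse = ", "), call. = FALSE)
  need_d <- c("donor_id", "age", "bmi")
  if (length(setdiff(need_d, names(don))))
    stop("donor table is missing column(s): ",
         paste(setdiff(need_d, names(don)), collapse = ", "), call. = FALSE)
  if (is.null(don$area_cm2)) {
    if (is.null(don$n_samples) || is.null(don$sample_area_mm2))
      stop("donor table needs area_cm2 or n_samples + sample_area_mm2",
           call. = FALSE)
    don$area_cm2 <- total_area(don$n_samples, don$sample_area_mm2)
  }
  orphans <- setdiff(mut$donor_id, don$donor_id)
  if (length(orphans))
    stop("mutation rows reference unknown donor(s): ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  bad_vaf <- which(!is.finite(mut$vaf) | mut$vaf <= 0 | mut$vaf > 1)
  if (length(bad_vaf))
    stop("VAF out of (0, 1] at mutation row(s): ",
         paste(utils::head(bad_vaf, 5), collapse = ", "), call. = FALSE)
  list(mutations = mut, donors = don)
}

# machine-readable provenance dropped into every CLI output directory
write_provenance <- function(out_dir, config) {
  jsonlite::write_json(
    list(package = "clonefate",
         version = as.character(utils::packageVersion("clonefate")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
}
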