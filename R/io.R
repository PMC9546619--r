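# All tabular interchange is TSV: UTF-8, "." decimal point, fixed
# documented headers, so reruns diff byte-identically.

PEPTIDE_COLUMNS <- c("sample_id", "protein_id", "peptide_sequence", "charge",
                     "endogenous_intensity", "reference_intensity",
                     "spike_amount_amol")

META_COLUMNS <- c("sample_id", "sample_type", "timepoint", "replicate",
                  "cell_equivalents", "injected_fraction", "treatment",
                  "fraction_index")

PROFILE_COLUMNS <- c("protein_id", "condition", "fraction_index", "intensity")

CONFIG_SCHEMA_VERSION <- "1.0"

.checkColumns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.numericColumn <- function(df, col, what) {
  raw <- as.character(df[[col]])
  v <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(v))
  if (length(bad))
    stop(sprintf("%s: malformed numeric value in column '%s' at row %d",
                 what, col, bad[1]), call. = FALSE)
  v
}

#' Validate a peptide measurement table
#'
#' Checks the column contract of the peptide-level quantification table:
#' finite non-negative intensities, positive charge, and non-negative
#' spike amounts (amol), with row numbers in every failure message.
#'
#' @param df data.frame with columns `sample_id`, `protein_id`,
#'   `peptide_sequence`, `charge`, `endogenous_intensity`,
#'   `reference_intensity`, `spike_amount_amol`.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validatePeptideTable <- function(df) {
  .checkColumns(df, PEPTIDE_COLUMNS, "peptide table")
  for (col in c("endogenous_intensity", "reference_intensity",
                "spike_amount_amol")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop(sprintf(
        "peptide table: column '%s' must be finite and >= 0 (row %d)",
        col, bad[1]), call. = FALSE)
  }
  bad <- which(df$charge < 1)
  if (length(bad))
    stop(sprintf("peptide table: charge must be >= 1 (row %d)", bad[1]),
         call. = FALSE)
  df
}

#' Read a peptide quantification table
#'
#' Reads a TSV of endogenous/reference intensity pairs with spike
#' amounts, one row per (sample, peptide, charge) measurement, and
#' enforces the table invariants. Row order is preserved.
#'
#' @param path path to the TSV file.
#' @return validated data.frame with the canonical peptide columns.
#' @seealso [validatePeptideTable()], [writeReport()]
#' @export
readPeptideTable <- function(path) {
  if (!file.exists(path)) stop("peptide table not found: ", path)
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE)
  .checkColumns(df, PEPTIDE_COLUMNS, "peptide table")
  if (nrow(df) == 0L) {
    out <- data.frame(sample_id = character(), protein_id = character(),
                      peptide_sequence = character(), charge = integer(),
                      endogenous_intensity = numeric(),
                      reference_intensity = numeric(),
                      spike_amount_amol = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(
    sample_id = df$sample_id,
    protein_id = df$protein_id,
    peptide_sequence = df$peptide_sequence,
    charge = as.integer(.numericColumn(df, "charge", "peptide table")),
    endogenous_intensity =
      .numericColumn(df, "endogenous_intensity", "peptide table"),
    reference_intensity =
      .numericColumn(df, "reference_intensity", "peptide table"),
    spike_amount_amol =
      .numericColumn(df, "spike_amount_amol", "peptide table"),
    stringsAsFactors = FALSE)
  validatePeptideTable(out)
}

#' Read a sample metadata table
#'
#' @param path path to a TSV with columns `sample_id`, `sample_type`
#'   (lysate / affinity_purification / bnpage_fraction), `timepoint`
#'   (minutes), `replicate`, `cell_equivalents` (cells represented at
#'   the spike point), `injected_fraction`, `treatment`,
#'   `fraction_index`.
#' @return validated data.frame.
#' @export
readSampleMeta <- function(path) {
  if (!file.exists(path)) stop("sample metadata not found: ", path)
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE)
  .checkColumns(df, META_COLUMNS, "sample metadata")
  if (nrow(df) == 0L) return(df)
  out <- data.frame(
    sample_id = df$sample_id,
    sample_type = df$sample_type,
    timepoint = .numericColumn(df, "timepoint", "sample metadata"),
    replicate = as.integer(.numericColumn(df, "replicate",
                                          "sample metadata")),
    cell_equivalents = .numericColumn(df, "cell_equivalents",
                                      "sample metadata"),
    injected_fraction = .numericColumn(df, "injected_fraction",
                                       "sample metadata"),
    treatment = df$treatment,
    fraction_index = suppressWarnings(as.integer(df$fraction_index)),
    stringsAsFactors = FALSE)
  validateSampleMeta(out)
}

#' @rdname readSampleMeta
#' @param df a sample metadata data.frame to validate in place.
#' @export
validateSampleMeta <- function(df) {
  .checkColumns(df, META_COLUMNS, "sample metadata")
  ok_type <- df$sample_type %in%
    c("lysate", "affinity_purification", "bnpage_fraction")
  if (any(!ok_type))
    stop(sprintf("sample metadata: unknown sample_type '%s' (row %d)",
                 df$sample_type[which(!ok_type)[1]], which(!ok_type)[1]),
         call. = FALSE)
  if (any(df$cell_equivalents <= 0))
    stop("sample metadata: cell_equivalents must be > 0", call. = FALSE)
  if (any(df$injected_fraction <= 0 | df$injected_fraction > 1))
    stop("sample metadata: injected_fraction must be in (0, 1]",
         call. = FALSE)
  if (any(df$timepoint < 0))
    stop("sample metadata: timepoint must be >= 0 minutes", call. = FALSE)
  is_bn <- df$sample_type == "bnpage_fraction"
  if (any(is_bn & is.na(df$fraction_index)) ||
      any(!is_bn & !is.na(df$fraction_index)))
    stop("sample metadata: fraction_index must be present iff sample_type ",
         "is bnpage_fraction", call. = FALSE)
  df
}

#' Read a complex configuration file
#'
#' Reads a YAML description of the complexes under study into a
#' [ComplexSet-class]. The schema is:
#'
#' ```yaml
#' schema_version: "1.0"
#' complexes:
#'   - name: receptor-core
#'     receptor: true
#'     receptor_oligomer: 3
#'     reference_policy: most_abundant
#'     members:
#'       TNFR1: 3
#'       TRADD: 1
#' ```
#'
#' A member listed without a multiplicity defaults to 1 (with a warning).
#' Duplicate complex names, or any number of receptor-flagged complexes
#' other than one, are configuration errors.
#'
#' @param path path to the YAML file.
#' @return a validated [ComplexSet-class].
#' @export
readComplexConfig <- function(path) {
  if (!file.exists(path)) stop("complex config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$complexes) || !length(cfg$complexes))
    stop("complex config: no complexes defined", call. = FALSE)
  if (!is.null(cfg$schema_version) &&
      !identical(as.character(cfg$schema_version), CONFIG_SCHEMA_VERSION))
    warning(sprintf("complex config schema_version '%s' (expected '%s')",
                    cfg$schema_version, CONFIG_SCHEMA_VERSION))
  defs <- lapply(cfg$complexes, function(cc) {
    if (is.null(cc$name)) stop("complex config: complex without a name")
    mem <- cc$members
    if (is.null(mem) || !length(mem))
      stop(sprintf("complex config: complex '%s' has no members", cc$name))
    mult <- vapply(seq_along(mem), function(i) {
      v <- mem[[i]]
      if (is.null(v) || (length(v) == 1L && is.na(v))) {
        warning(sprintf(
          "complex '%s': member '%s' has no multiplicity, defaulting to 1",
          cc$name, names(mem)[i]), call. = FALSE)
        1L
      } else as.integer(v)
    }, integer(1))
    ComplexDefinition(
      complexName = cc$name,
      members = setNames(mult, names(mem)),
      referencePolicy = if (is.null(cc$reference_policy)) "most_abundant"
                        else cc$reference_policy,
      receptorFlag = isTRUE(cc$receptor),
      receptorOligomer = if (is.null(cc$receptor_oligomer)) 3L
                         else as.integer(cc$receptor_oligomer))
  })
  nm <- vapply(defs, complexName, character(1))
  if (anyDuplicated(nm))
    stop(sprintf("complex config: duplicated complex name '%s'",
                 nm[anyDuplicated(nm)]), call. = FALSE)
  ComplexSet(defs)
}

#' Write a complex configuration file
#'
#' Inverse of [readComplexConfig()]; round-trips every field.
#'
#' @param complexSet a [ComplexSet-class].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeComplexConfig <- function(complexSet, path) {
  stopifnot(is(complexSet, "ComplexSet"))
  cfg <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    complexes = lapply(complexSet@complexes, function(cc) {
      list(name = complexName(cc),
           receptor = isReceptor(cc),
           receptor_oligomer = as.integer(receptorOligomer(cc)),
           reference_policy = referencePolicy(cc),
           members = as.list(setNames(as.integer(members(cc)),
                                      names(members(cc)))))
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read BNPAGE migration profiles
#'
#' @param path TSV with columns `protein_id`, `condition`,
#'   `fraction_index` (1-based gel slice), `intensity`.
#' @return long data.frame ordered by protein, condition, fraction.
#' @seealso [profilesToMatrix()]
#' @export
readBnpageProfiles <- function(path) {
  if (!file.exists(path)) stop("profile table not found: ", path)
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE)
  .checkColumns(df, PROFILE_COLUMNS, "BNPAGE profile table")
  out <- data.frame(
    protein_id = df$protein_id,
    condition = df$condition,
    fraction_index = as.integer(.numericColumn(df, "fraction_index",
                                               "BNPAGE profile table")),
    intensity = .numericColumn(df, "intensity", "BNPAGE profile table"),
    stringsAsFactors = FALSE)
  if (any(out$intensity < 0))
    stop("BNPAGE profile table: intensities must be >= 0", call. = FALSE)
  if (any(out$fraction_index < 1))
    stop("BNPAGE profile table: fraction_index is 1-based", call. = FALSE)
  out[order(out$protein_id, out$condition, out$fraction_index), ,
      drop = FALSE]
}

#' Reshape long BNPAGE profiles to a fraction-by-protein matrix
#'
#' @param profiles long data.frame as from [readBnpageProfiles()].
#' @param condition single condition label to extract.
#' @return numeric matrix, rows = fraction index, columns = proteins.
#' @export
profilesToMatrix <- function(profiles, condition) {
  sub <- profiles[profiles$condition == condition, , drop = FALSE]
  if (!nrow(sub)) stop("no profiles for condition '", condition, "'")
  prot <- sort(unique(sub$protein_id))
  nf <- max(sub$fraction_index)
  m <- matrix(0, nrow = nf, ncol = length(prot),
              dimnames = list(NULL, prot))
  m[cbind(sub$fraction_index, match(sub$protein_id, prot))] <- sub$intensity
  m
}

#' Write a TSV with the package's canonical conventions
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write a pipeline results report
#'
#' Writes every element of `results` (a named list of data.frames) as
#' `<name>.tsv` under `outDir`, plus a machine-readable `summary.json`
#' recording the seed, a hash of the run parameters, and the parameters
#' themselves. Reruns with identical inputs and seed produce
#' byte-identical files.
#'
#' @param results named list of data.frames.
#' @param outDir output directory (created if absent).
#' @param seed integer seed the run used.
#' @param params named list of stage parameters to record.
#' @return character vector of written file paths, invisibly.
#' @export
writeReport <- function(results, outDir, seed = NA_integer_,
                        params = list()) {
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outDir))
      stop("cannot create output directory: ", outDir)
  }
  if (file.access(outDir, 2) != 0)
    stop("output directory is not writable: ", outDir)
  stopifnot(is.list(results), !is.null(names(results)))
  paths <- character()
  for (nm in names(results)) {
    p <- file.path(outDir, paste0(nm, ".tsv"))
    writeTsv(results[[nm]], p)
    paths <- c(paths, p)
  }
  cfg_json <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  summary <- list(
    package = "contextomics",
    schema_version = CONFIG_SCHEMA_VERSION,
    seed = if (is.na(seed)) NULL else as.integer(seed),
    config_hash = hash,
    params = params,
    tables = basename(paths))
  sp <- file.path(outDir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, sp))
}
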