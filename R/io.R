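#' Read a PRS weight table
#'
#' Reads a tab-separated file of per-variant effect sizes, the canonical
#' five-column layout used by published breast-cancer PRS weight sets
#' (77, 313, 2803 and 3820 SNP scales): `variant_id`, `chromosome`,
#' `position`, `effect_allele`, `other_allele`, `beta`.  `beta` is on the
#' per-effect-allele log-odds scale; positions are 1-based and carried as
#' metadata only (variant matching is by id, see [harmonize()]).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `weight_table`: a data.frame with the six columns above, one row
#'   per variant, validated (unique ids, ACGT alleles, effect != other,
#'   finite beta).
#' @seealso [write_weights()], [harmonize()], [simulate_weights()]
#' @export
read_weights <- function(path) {
  df <- read_tsv_checked(path, c("variant_id", "chromosome", "position",
                                 "effect_allele", "other_allele", "beta"))
  weight_table(df, source = path)
}

#' Construct and validate a weight table
#'
#' @param df data.frame with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `beta`.
#' @param source optional provenance string kept as an attribute.
#' @return A validated `weight_table`.
#' @export
weight_table <- function(df, source = NULL) {
  need <- c("variant_id", "chromosome", "position",
            "effect_allele", "other_allele", "beta")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weight table is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$variant_id <- as.character(df$variant_id)
  df$chromosome <- as.character(df$chromosome)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))

  bad <- which(!(df$effect_allele %in% c("A", "C", "G", "T")) |
               !(df$other_allele %in% c("A", "C", "G", "T")))
  if (length(bad))
    stop("non-ACGT allele at line ", bad[1] + 1L, " (variant ",
         df$variant_id[bad[1]], ")")
  if (any(df$effect_allele == df$other_allele)) {
    i <- which(df$effect_allele == df$other_allele)[1]
    stop("effect and other allele identical at line ", i + 1L)
  }
  beta <- suppressWarnings(as.numeric(df$beta))
  bad <- which(is.na(beta) | !is.finite(beta))
  if (length(bad))
    stop("non-numeric or non-finite beta at line ", bad[1] + 1L)
  df$beta <- beta
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos)) stop("non-integer position at line ",
                       which(is.na(pos))[1] + 1L)
  df$position <- pos
  dup <- df$variant_id[duplicated(df$variant_id)]
  if (length(dup))
    stop("duplicated variant_id: ", paste(unique(dup), collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("weight_table", "data.frame"), source = source)
}

#' Write a weight table as TSV
#' @param x A `weight_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(x, path) {
  stopifnot(inherits(x, "weight_table"))
  write_tsv_plain(as.data.frame(x), path)
}

#' Read an age-specific rate table
#'
#' Reads registry-style age-specific rates (incidence from e.g. NORDCAN, or
#' all-cause mortality from e.g. GHO) published per 100,000 person-years in
#' contiguous half-open integer-year age bins `[age_lo, age_hi)`.  Rates are
#' converted to per-person-year on read (exactly x 1e-5); within a bin the
#' hazard is treated as constant.
#'
#' @param path TSV with header columns `age_lo`, `age_hi`, `rate_per_100k`.
#' @param kind `"incidence"` or `"mortality"`.
#' @return A `rate_table`: data.frame with `age_lo`, `age_hi`, `rate`
#'   (per person-year) and a `kind` attribute.
#' @seealso [rate_table()], [synthetic_rates()]
#' @export
read_rate_table <- function(path, kind = c("incidence", "mortality")) {
  kind <- match.arg(kind)
  df <- read_tsv_checked(path, c("age_lo", "age_hi", "rate_per_100k"))
  rate_table(df$age_lo, df$age_hi, df$rate_per_100k / 1e5, kind = kind)
}

#' Construct and validate a rate table
#'
#' @param age_lo,age_hi Integer year bounds of contiguous half-open bins
#'   `[age_lo, age_hi)`.
#' @param rate Hazard rate per person-year (already converted from any
#'   per-100k publication units).
#' @param kind `"incidence"` or `"mortality"`.
#' @return A `rate_table`.
#' @export
rate_table <- function(age_lo, age_hi, rate, kind = c("incidence", "mortality")) {
  kind <- match.arg(kind)
  age_lo <- as.integer(age_lo); age_hi <- as.integer(age_hi)
  if (anyNA(age_lo) || anyNA(age_hi)) stop("non-integer age bounds")
  o <- order(age_lo)
  age_lo <- age_lo[o]; age_hi <- age_hi[o]; rate <- as.numeric(rate)[o]
  if (any(age_hi <= age_lo)) stop("bin with age_hi <= age_lo")
  if (length(age_lo) > 1L) {
    gap <- which(age_lo[-1] != age_hi[-length(age_hi)])
    if (length(gap))
      stop("rate table bins have a gap or overlap between ages ",
           age_hi[gap[1]], " and ", age_lo[gap[1] + 1L])
  }
  if (any(!is.finite(rate)) || any(rate < 0)) stop("rates must be finite and >= 0")
  structure(data.frame(age_lo = age_lo, age_hi = age_hi, rate = rate),
            class = c("rate_table", "data.frame"), kind = kind)
}

#' Write a rate table as TSV (in per-100k publication units)
#' @param x A `rate_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(x, path) {
  stopifnot(inherits(x, "rate_table"))
  out <- data.frame(age_lo = x$age_lo, age_hi = x$age_hi,
                    rate_per_100k = x$rate * 1e5)
  write_tsv_plain(out, path)
}

#' Look up the hazard rate at given ages
#'
#' Step-function lookup: age `a` falls in the bin with
#' `age_lo <= a < age_hi`.
#'
#' @param x A `rate_table`.
#' @param age Numeric vector of ages.
#' @return Hazard per person-year at each age.
#' @export
rate_at <- function(x, age) {
  stopifnot(inherits(x, "rate_table"))
  i <- findInterval(age, c(x$age_lo, x$age_hi[nrow(x)]),
                    rightmost.closed = FALSE)
  out_of_range <- i < 1L | i > nrow(x) | age >= x$age_hi[nrow(x)]
  if (any(out_of_range))
    stop("age outside rate table span [", x$age_lo[1], ", ",
         x$age_hi[nrow(x)], ")")
  x$rate[i]
}

## yearly step-function expansion: one rate per integer year of age
rate_grid <- function(x) {
  ages <- seq.int(x$age_lo[1], x$age_hi[nrow(x)] - 1L)
  list(ages = ages, rate = rate_at(x, ages))
}

#' Read a phenotype table
#'
#' TSV with header columns `sample_id`, `status` (`case`/`control`),
#' `entry_age`, `exit_age`, `event` (0/1 or TRUE/FALSE); optional `prs_raw`,
#' `prs_z`.  `exit_age` is the age at diagnosis for cases and the age at last
#' follow-up for controls; `entry_age` is the age at cohort entry
#' (left-truncation age).
#'
#' @param path Path to the TSV.
#' @return A `cohort_table` data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "status", "entry_age",
                                 "exit_age", "event"))
  cohort_table(df)
}

#' Construct and validate a cohort table
#'
#' @param df data.frame with at least `sample_id`, `status`, `entry_age`,
#'   `exit_age`, `event`; optional `prs_raw` and `prs_z`.
#' @return A validated `cohort_table`.
#' @export
cohort_table <- function(df) {
  need <- c("sample_id", "status", "entry_age", "exit_age", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$status <- as.character(df$status)
  if (!all(df$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  df$entry_age <- as.numeric(df$entry_age)
  df$exit_age <- as.numeric(df$exit_age)
  ev <- df$event
  if (is.character(ev)) ev <- trimws(ev)
  evn <- suppressWarnings(as.numeric(ev))
  df$event <- ifelse(!is.na(evn), evn != 0, as.logical(ev))
  if (anyNA(df$event)) stop("event must be 0/1 or TRUE/FALSE")
  if (any(df$entry_age < 0)) stop("negative entry_age")
  bad <- which(df$exit_age <= df$entry_age)
  if (length(bad))
    stop("exit_age <= entry_age for sample ", df$sample_id[bad[1]])
  if (any(df$event & df$status != "case"))
    stop("event = TRUE requires status = 'case'")
  for (col in c("prs_raw", "prs_z"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  rownames(df) <- NULL
  keep <- intersect(c(need, "prs_raw", "prs_z"), names(df))
  structure(df[keep], class = c("cohort_table", "data.frame"))
}

#' Write a cohort table as TSV
#' @param x A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path) {
  stopifnot(inherits(x, "cohort_table"))
  out <- as.data.frame(x)
  out$event <- as.integer(out$event)
  write_tsv_plain(out, path)
}

#' Construct a genotype dosage matrix
#'
#' @param dosage Numeric matrix, samples x variants, values 0/1/2/NA (number
#'   of copies of the counted allele).
#' @param sample_ids,variant_ids Row and column identities.
#' @param alleles Optional data.frame with `variant_id`, `allele1`
#'   (the counted allele), `allele2`; NA alleles mark variants whose
#'   orientation is unknown.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            variant_ids = colnames(dosage), alleles = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids) || is.null(variant_ids))
    stop("sample and variant ids are required")
  if (length(sample_ids) != nrow(dosage) || length(variant_ids) != ncol(dosage))
    stop("dimension mismatch between dosage matrix and ids")
  ok <- is.na(dosage) | dosage == 0 | dosage == 1 | dosage == 2
  if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
  if (is.null(alleles)) {
    alleles <- data.frame(variant_id = as.character(variant_ids),
                          allele1 = NA_character_, allele2 = NA_character_)
  } else {
    stopifnot(all(c("variant_id", "allele1", "allele2") %in% names(alleles)))
    alleles <- alleles[match(variant_ids, alleles$variant_id),
                       c("variant_id", "allele1", "allele2")]
    if (anyNA(alleles$variant_id)) stop("alleles missing for some variants")
  }
  dimnames(dosage) <- list(as.character(sample_ids), as.character(variant_ids))
  structure(list(dosage = dosage,
                 sample_ids = as.character(sample_ids),
                 variant_ids = as.character(variant_ids),
                 alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$variant_ids), "variants\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness %.2f%%, alleles %s\n", 100 * miss,
              if (all(is.na(x$alleles$allele1))) "unknown" else "declared"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read a genotype dosage matrix from TSV
#'
#' First column `sample_id`; one column per variant with cells 0/1/2/NA
#' ("NA" is the only missing-value sentinel).  Column headers of the form
#' `rsID_EA_OA` (e.g. `rs123_A_G`) declare the counted (effect-orientation)
#' allele and the other allele; plain headers leave the alleles unknown,
#' which [harmonize()] treats conservatively.
#'
#' @param path Path to the TSV.
#' @return A `genotype_matrix`.
#' @export
read_dosage_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = "NA")
  if (names(df)[1] != "sample_id")
    stop("first column of a dosage file must be 'sample_id'")
  ids <- df$sample_id
  mat <- as.matrix(df[-1])
  bad <- !(is.na(mat) | mat %in% c("0", "1", "2"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown dosage symbol '", mat[bad][1], "' at line ", idx[1] + 1L,
         " (only 0/1/2/NA accepted)")
  }
  storage.mode(mat) <- "numeric"
  hdr <- colnames(mat)
  parsed <- regmatches(hdr, regexec("^(.+)_([ACGT])_([ACGT])$", hdr))
  has_al <- lengths(parsed) == 4L
  vids <- ifelse(has_al, vapply(parsed, function(p) if (length(p)) p[2] else NA_character_,
                                ""), hdr)
  alleles <- data.frame(
    variant_id = vids,
    allele1 = ifelse(has_al, vapply(parsed, function(p) if (length(p)) p[3] else NA_character_, ""), NA_character_),
    allele2 = ifelse(has_al, vapply(parsed, function(p) if (length(p)) p[4] else NA_character_, ""), NA_character_))
  genotype_matrix(mat, sample_ids = ids, variant_ids = vids, alleles = alleles)
}

#' Write a genotype dosage matrix as TSV
#'
#' Variants with declared alleles get `rsID_EA_OA` headers so that
#' write-then-read is the identity.
#'
#' @param x A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  hdr <- ifelse(is.na(x$alleles$allele1), x$variant_ids,
                paste(x$variant_ids, x$alleles$allele1, x$alleles$allele2,
                      sep = "_"))
  out <- data.frame(sample_id = x$sample_ids, check.names = FALSE)
  m <- x$dosage
  mode(m) <- "integer"
  colnames(m) <- hdr
  out <- cbind(out, as.data.frame(m, check.names = FALSE))
  write_tsv_plain(out, path)
}

#' Read genotype dosages from a VCF
#'
#' Converts diploid GT fields to counts of the ALT allele; the declared
#' counted allele is ALT and the other allele REF, so downstream
#' harmonization can reorient against a weight table.  Multiallelic records
#' are dropped with a warning.  Requires the `vcfR` package.
#'
#' @param path Path to a VCF (v4.x, plain or bgzipped).
#' @return A `genotype_matrix`.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) dropped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(a == "1", na.rm = TRUE) + 0, numeric(1)))
  }
  dos <- t(matrix(count_alt(as.vector(gt)), nrow = nrow(gt)))  # samples x variants
  vids <- fix[, "ID"]
  noid <- is.na(vids) | vids == "."
  vids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  alleles <- data.frame(variant_id = vids,
                        allele1 = fix[, "ALT"], allele2 = fix[, "REF"])
  genotype_matrix(dos, sample_ids = colnames(gt), variant_ids = vids,
                  alleles = alleles)
}

## ---- internal helpers -----------------------------------------------------

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(basename(path), ": missing column(s): ", paste(miss, collapse = ", "))
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
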