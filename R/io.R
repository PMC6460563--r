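#' Read allele-specific count table
#'
#' Expects a TSV with columns `sample_id`, `chrom`, `pos` (1-based), `ref`,
#' `alt`, `ref_count`, `alt_count`. Rows with negative counts or
#' non-positive positions are rejected with their line numbers.
#'
#' @param path Path to the TSV file.
#' @return Counts tibble.
#' @export
read_counts_tsv <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c(
    "sample_id", "chrom", "pos", "ref", "alt", "ref_count", "alt_count"
  )
  miss <- setdiff(required, names(counts))
  if (length(miss) > 0) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(counts$ref_count < 0 | counts$alt_count < 0)
  if (length(bad) > 0) {
    stop(path, ": negative read count at line(s) ",
      paste(utils::head(bad + 1, 5), collapse = ", "),
      call. = FALSE
    )
  }
  bad_pos <- which(counts$pos < 1)
  if (length(bad_pos) > 0) {
    stop(path, ": non-positive position at line(s) ",
      paste(utils::head(bad_pos + 1, 5), collapse = ", "),
      call. = FALSE
    )
  }
  counts
}

#' Read a BED file of intervals
#'
#' 0-based half-open intervals; the fourth column (name), when present, is
#' returned as `gene_id`. Intervals with `start >= end` are rejected.
#'
#' @param path Path to the BED file.
#' @return Tibble with `chrom`, `start`, `end` and optionally `gene_id`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = FALSE, show_col_types = FALSE, comment = "#"
  )
  if (ncol(bed) < 3) stop(path, ": BED needs >= 3 columns", call. = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "gene_id"
  bad <- which(bed$start >= bed$end)
  if (length(bad) > 0) {
    stop(path, ": start >= end at line(s) ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  bed[seq_len(min(4, ncol(bed)))]
}

write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "gene_id", "name"), names(bed))
  readr::write_tsv(bed[cols], path, col_names = FALSE)
}

gt_index <- function(allele, ref, alt) {
  ifelse(allele == ref, "0", ifelse(allele == alt, "1", "."))
}

# Minimal VCF 4.2 with GT-only FORMAT: one row per (trio, site), samples are
# daughter/father/mother of every trio (missing "./." outside the trio's own
# sites). Father written in the hemizygous single-allele dialect.
write_genotypes_vcf <- function(genotypes, trios, path) {
  samples <- as.vector(t(as.matrix(trios[, c("daughter", "father", "mother")])))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=xskew synthetic cohort generator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(
      c(
        "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", samples
      ),
      collapse = "\t"
    )
  )
  g <- genotypes
  d_alleles <- strsplit(g$daughter_gt, "/", fixed = TRUE)
  m_alleles <- strsplit(g$mother_gt, "/", fixed = TRUE)
  d_gt <- paste(
    gt_index(vapply(d_alleles, `[`, "", 1), g$ref, g$alt),
    gt_index(vapply(d_alleles, `[`, "", 2), g$ref, g$alt),
    sep = "/"
  )
  m_gt <- ifelse(
    is.na(g$mother_gt), "./.",
    paste(
      gt_index(vapply(m_alleles, `[`, "", 1), g$ref, g$alt),
      gt_index(vapply(m_alleles, `[`, "", 2), g$ref, g$alt),
      sep = "/"
    )
  )
  f_gt <- gt_index(g$father_allele, g$ref, g$alt)
  gt_by_sample <- matrix("./.", nrow = nrow(g), ncol = length(samples))
  colnames(gt_by_sample) <- samples
  trio_lookup <- trios[match(g$trio_id, trios$trio_id), ]
  for (i in seq_len(nrow(g))) {
    gt_by_sample[i, trio_lookup$daughter[i]] <- d_gt[i]
    gt_by_sample[i, trio_lookup$father[i]] <- f_gt[i]
    gt_by_sample[i, trio_lookup$mother[i]] <- m_gt[i]
  }
  body <- paste(
    g$chrom, g$pos, ".", g$ref, g$alt, ".", "PASS", ".", "GT",
    apply(gt_by_sample, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  ord <- order(g$pos)
  writeLines(c(header, body[ord]), path)
}

numeric_gt_to_bases <- function(gt, ref, alt) {
  # "0/1", "1|0", "1", "./." -> allele strings like "A/G", "G", NA
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) == 0 || any(p == "." | is.na(p))) {
      return(NA_character_)
    }
    al <- ifelse(p == "0", ref[i], ifelse(p == "1", alt[i], NA))
    if (any(is.na(al))) {
      return(NA_character_)
    }
    paste(sort(al), collapse = "/")
  }, character(1))
}

#' Read trio genotypes from a VCF file
#'
#' Parses a multi-sample VCF (GT field only) into the trio genotype table the
#' phaser consumes. Fathers may be called in either hemizygous dialect --
#' a single allele (`"1"`) or a homozygous diploid call (`"1/1"`); diploid
#' heterozygous father calls are preserved and flagged inconsistent
#' downstream. Multi-allelic records are excluded with a warning; rows with a
#' missing daughter genotype are dropped with a message.
#'
#' @param path Path to the VCF.
#' @param trios Tibble mapping `trio_id` to the `daughter`, `father` and
#'   `mother` sample names in the VCF.
#' @return Genotypes tibble as produced by [generate_trio_genotypes()]
#'   (without the generator's truth annotations).
#' @export
read_genotypes_vcf <- function(path, trios) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) excluded", call. = FALSE)
  }
  keep <- !multi
  missing_samples <- setdiff(
    unlist(trios[, c("daughter", "father", "mother")]), colnames(gt)
  )
  if (length(missing_samples) > 0) {
    stop(path, ": sample(s) absent from VCF: ",
      paste(missing_samples, collapse = ", "),
      call. = FALSE
    )
  }
  out <- purrr::pmap_dfr(trios[, c("trio_id", "daughter", "father", "mother")],
    function(trio_id, daughter, father, mother) {
    ref <- fix$REF[keep]
    alt <- fix$ALT[keep]
    d <- numeric_gt_to_bases(gt[keep, daughter], ref, alt)
    m <- numeric_gt_to_bases(gt[keep, mother], ref, alt)
    f <- numeric_gt_to_bases(gt[keep, father], ref, alt)
    # collapse homozygous-diploid father dialect to a single allele
    f_parts <- strsplit(ifelse(is.na(f), "", f), "/", fixed = TRUE)
    f <- vapply(f_parts, function(p) {
      if (length(p) == 0 || p[1] == "") {
        NA_character_
      } else if (length(p) == 1 || p[1] == p[2]) {
        p[1]
      } else {
        paste(p, collapse = "/") # het father kept verbatim
      }
    }, character(1))
    tibble::tibble(
      trio_id = trio_id,
      sample_id = daughter,
      chrom = fix$CHROM[keep],
      pos = as.integer(fix$POS[keep]),
      ref = ref, alt = alt,
      daughter_gt = d, mother_gt = m, father_allele = f
    )
  })
  n_missing <- sum(is.na(out$daughter_gt))
  if (n_missing > 0) {
    message(
      n_missing,
      " record(s) with missing daughter genotype were dropped"
    )
  }
  out[!is.na(out$daughter_gt), ]
}

#' Write a synthetic cohort bundle to disk
#'
#' Serializes a cohort as plain-text files: `genotypes.vcf` (GT-only
#' multi-sample VCF), `counts.tsv`, `exons.bed` and `par.bed` (0-based
#' half-open), `trios.tsv`, and the ground truth as
#' `truth_individuals.tsv`, `truth_genes.tsv`, `truth_variable_escape.tsv`
#' and a JSON summary.
#'
#' @param cohort An `xi_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "xi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_genotypes_vcf(cohort$genotypes, cohort$trios, p("genotypes.vcf"))
  readr::write_tsv(cohort$counts, p("counts.tsv"))
  write_bed(cohort$exons, p("exons.bed"))
  write_bed(cohort$par, p("par.bed"))
  readr::write_tsv(cohort$trios, p("trios.tsv"))
  readr::write_tsv(cohort$truth$individuals, p("truth_individuals.tsv"))
  readr::write_tsv(cohort$truth$genes, p("truth_genes.tsv"))
  readr::write_tsv(cohort$truth$variable_escape, p("truth_variable_escape.tsv"))
  jsonlite::write_json(
    list(
      n_trios = cohort$config$n_trios,
      n_cells = cohort$config$n_cells,
      seed = cohort$config$seed,
      n_sites = nrow(cohort$genotypes),
      n_count_records = nrow(cohort$counts),
      gene_status_counts = as.list(table(cohort$truth$genes$status))
    ),
    p("truth_summary.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Read and validate the pipeline input files
#'
#' Loads genotypes (VCF), counts (TSV), exon and PAR annotation (BED) and
#' the trio sample map, and cross-checks that every counts sample is either
#' a known daughter or mother.
#'
#' @param genotypes_vcf,counts_tsv,exons_bed,par_bed,trios_tsv File paths.
#' @return List with `genotypes`, `counts`, `exons`, `par`, `trios`.
#' @export
read_inputs <- function(genotypes_vcf, counts_tsv, exons_bed, par_bed,
                        trios_tsv) {
  trios <- readr::read_tsv(trios_tsv, show_col_types = FALSE)
  stopifnot(all(c("trio_id", "daughter", "father", "mother") %in% names(trios)))
  counts <- read_counts_tsv(counts_tsv)
  known <- c(trios$daughter, trios$mother)
  unknown <- setdiff(unique(counts$sample_id), known)
  if (length(unknown) > 0) {
    stop(counts_tsv, ": unknown sample id(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  list(
    genotypes = read_genotypes_vcf(genotypes_vcf, trios),
    counts = counts,
    exons = read_bed(exons_bed),
    par = read_bed(par_bed),
    trios = trios
  )
}
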