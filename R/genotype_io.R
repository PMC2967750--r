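#' Construct a genotype matrix
#'
#' The central genotype container: an integer dosage grid (samples x
#' variants) with codes 0 (reference homozygote), 1 (heterozygote),
#' 2 (alternate homozygote) and `NA` for missing calls, plus per-variant
#' metadata.
#'
#' @param dosages integer matrix, rows = samples, columns = variants;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`. One row per column of `dosages`.
#' @param sample_ids character vector of unique sample identifiers,
#'   one per row of `dosages`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(is.data.frame(variants))
  req <- c("variant_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  variants <- as.data.frame(variants)[, req]
  variants$variant_id <- as.character(variants$variant_id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  sample_ids <- as.character(sample_ids)
  if (nrow(dosages) != length(sample_ids)) {
    stop("dosage grid has ", nrow(dosages), " rows but ", length(sample_ids),
         " sample ids")
  }
  if (ncol(dosages) != nrow(variants)) {
    stop("dosage grid has ", ncol(dosages), " columns but ", nrow(variants),
         " variant records")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant ids: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "))
  }
  if (any(variants$pos < 1L, na.rm = TRUE)) stop("variant pos must be >= 1")
  bad <- !(dosages %in% c(0L, 1L, 2L)) & !is.na(dosages)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("dosage out of {0,1,2,NA} at sample '", sample_ids[idx[1]],
         "', variant '", variants$variant_id[idx[2]], "'")
  }
  dimnames(dosages) <- list(sample_ids, variants$variant_id)
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants;",
      sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file into a [genotype_matrix()].
#' Dosage is the count of alternate alleles per diploid call; `./.` (or
#' `.|.`) becomes missing. Phased (`|`) and unphased (`/`) separators are
#' treated identically.
#'
#' Multi-allelic sites and non-diploid calls are rejected: the method is
#' defined for biallelic array SNPs, and splitting multi-allelic records
#' would silently change frequency estimates.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) == 0L) stop("VCF has no samples: ", path)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt_list)
  if (any(n_alt != 1L)) {
    bad <- rownames(vcf)[n_alt != 1L]
    stop("multi-allelic site(s) not supported: ", paste(bad, collapse = ", "))
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    variant_id = rownames(vcf),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(alt_list, function(a) as.character(a)[1], character(1)),
    stringsAsFactors = FALSE
  )
  # gt is variants x samples of strings like "0/1", "1|1", "./."
  gt_flat <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  alleles <- strsplit(gt_flat, "/", fixed = TRUE)
  ploidy <- lengths(alleles)
  if (any(ploidy != 2L)) {
    stop("non-diploid GT call(s) found (ploidy ",
         paste(unique(ploidy[ploidy != 2L]), collapse = ","), ")")
  }
  a <- matrix(unlist(alleles), nrow = 2L)
  dos <- ifelse(a[1, ] == "." | a[2, ] == ".", NA_integer_,
                as.integer(a[1, ] != "0") + as.integer(a[2, ] != "0"))
  dosages <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  genotype_matrix(t(dosages), variants, colnames(gt))
}

#' Read genotypes from a dosage table
#'
#' Reads the plain-text dosage dialect: a TSV whose first column is the
#' sample id, whose header names the variants, and whose body holds
#' `{0, 1, 2, NA}`. An optional companion metadata TSV (columns
#' `variant_id`, `chrom`, `pos`, optionally `ref`, `alt`) supplies variant
#' coordinates; without it, placeholder coordinates are used.
#'
#' @param path path to the dosage TSV.
#' @param meta_path optional path to the variant metadata TSV.
#' @return a [genotype_matrix()].
#' @export
read_dosage_table <- function(path, meta_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("dosage table needs a sample column plus >= 1 variant column")
  sample_ids <- tab[[1]]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id in dosage table: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- as.matrix(tab[, -1, drop = FALSE])
  vals <- matrix(trimws(body), nrow(body), ncol(body),
                 dimnames = dimnames(body))
  ok <- matrix(is.na(vals) | vals %in% c("0", "1", "2", "NA", ""),
               nrow(vals), ncol(vals))
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid dosage value '", vals[idx[1], idx[2]], "' at row '",
         sample_ids[idx[1]], "', column '", colnames(body)[idx[2]], "'")
  }
  dosages <- matrix(suppressWarnings(as.integer(vals)),
                    nrow = nrow(body), ncol = ncol(body))
  variant_ids <- colnames(body)
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    m <- match(variant_ids, meta$variant_id)
    if (anyNA(m)) {
      stop("variant(s) absent from metadata: ",
           paste(variant_ids[is.na(m)], collapse = ", "))
    }
    variants <- data.frame(
      variant_id = variant_ids,
      chrom = as.character(meta$chrom[m]),
      pos = as.integer(meta$pos[m]),
      ref = if ("ref" %in% names(meta)) as.character(meta$ref[m]) else "N",
      alt = if ("alt" %in% names(meta)) as.character(meta$alt[m]) else "N",
      stringsAsFactors = FALSE
    )
  } else {
    variants <- data.frame(variant_id = variant_ids, chrom = "chrUn",
                           pos = seq_along(variant_ids), ref = "N", alt = "N",
                           stringsAsFactors = FALSE)
  }
  genotype_matrix(dosages, variants, sample_ids)
}

#' Write a genotype matrix as a dosage table
#'
#' Inverse of [read_dosage_table()]; round-trips exactly, including the
#' missingness pattern.
#'
#' @param gm a [genotype_matrix()].
#' @param path output TSV path.
#' @param meta_path optional path for the companion variant metadata TSV.
#' @export
write_dosage_table <- function(gm, path, meta_path = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- data.frame(sample_id = gm$sample_ids, gm$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- gm$variants
    names(meta) <- c("variant_id", "chrom", "pos", "ref", "alt")
    utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' BED4 or wider: `chrom start end name`, 0-based half-open. Rows sharing
#' a gene symbol on the same chromosome are merged to their union
#' interval; the same symbol on two chromosomes is an error.
#'
#' @param path path to the BED file.
#' @return data.frame of class `gene_intervals` with columns `symbol`,
#'   `chrom`, `start`, `end`.
#' @export
read_gene_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  empty <- data.frame(symbol = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(structure(empty, class = c("gene_intervals", "data.frame")))
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 4L)) {
    stop("BED line with fewer than 4 columns: line ",
         which(lengths(fields) < 4L)[1])
  }
  bed <- data.frame(
    symbol = vapply(fields, `[`, character(1), 4L),
    chrom = vapply(fields, `[`, character(1), 1L),
    start = as.integer(vapply(fields, `[`, character(1), 2L)),
    end = as.integer(vapply(fields, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(bed$start)) || any(is.na(bed$end))) {
    stop("non-numeric start/end in BED file")
  }
  if (any(bed$start >= bed$end)) {
    bad <- bed$symbol[bed$start >= bed$end]
    stop("BED interval with start >= end for: ", paste(bad, collapse = ", "))
  }
  merged <- do.call(rbind, lapply(split(bed, bed$symbol), function(g) {
    if (length(unique(g$chrom)) > 1L) {
      stop("gene symbol '", g$symbol[1], "' appears on multiple chromosomes: ",
           paste(unique(g$chrom), collapse = ", "))
    }
    data.frame(symbol = g$symbol[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  # preserve original first-appearance order of symbols
  merged <- merged[match(unique(bed$symbol), merged$symbol), ]
  rownames(merged) <- NULL
  structure(merged, class = c("gene_intervals", "data.frame"))
}

#' Read a candidate gene list
#'
#' One symbol per line, `#` comments allowed. The list stands in for an
#' external pharmacogene knowledge filter (a pre-ranked gene list): only
#' genes on it are carried into mapping and all downstream analyses.
#' Symbols absent from the gene annotation are dropped with a warning.
#'
#' @param path path to the gene-list text file.
#' @param genes a `gene_intervals` annotation to validate against, or
#'   `NULL` to skip validation.
#' @return deduplicated, order-preserving character vector of symbols.
#' @export
read_gene_list <- function(path, genes = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  syms <- trimws(lines)
  syms <- syms[nzchar(syms)]
  syms <- unique(syms)
  if (!is.null(genes)) {
    unknown <- setdiff(syms, genes$symbol)
    if (length(unknown) > 0L) {
      warning("gene symbol(s) absent from annotation, dropped: ",
              paste(unknown, collapse = ", "))
      syms <- setdiff(syms, unknown)
    }
  }
  if (length(syms) == 0L) stop("knowledge filter removed all genes")
  syms
}

#' Read a phenotype table
#'
#' TSV with columns `sample_id` and `dose_mg_per_day` (stable maintenance
#' dose, mg/day, strictly positive). Rows are reconciled to the genotype
#' matrix by id, never by position; phenotype rows without genotypes are
#' rejected (or dropped with a warning).
#'
#' @param path path to the phenotype TSV.
#' @param gm optional [genotype_matrix()] to reconcile against.
#' @param drop_extra if `TRUE`, phenotype rows absent from `gm` are dropped
#'   with a warning instead of raising an error.
#' @return data.frame with columns `sample_id`, `dose` ordered to match
#'   `gm$sample_ids` when `gm` is supplied.
#' @export
read_phenotypes <- function(path, gm = NULL, drop_extra = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("sample_id", "dose_mg_per_day")
  if (!all(req %in% names(tab))) {
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  }
  phen <- data.frame(sample_id = as.character(tab$sample_id),
                     dose = as.numeric(tab$dose_mg_per_day),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(phen$sample_id)) stop("duplicate sample id in phenotype table")
  if (any(!is.finite(phen$dose)) || any(phen$dose <= 0)) {
    stop("stable dose must be a finite value > 0 mg/day")
  }
  if (!is.null(gm)) {
    extra <- setdiff(phen$sample_id, gm$sample_ids)
    if (length(extra) > 0L) {
      if (drop_extra) {
        warning("phenotype rows without genotypes dropped: ",
                paste(extra, collapse = ", "))
        phen <- phen[!phen$sample_id %in% extra, ]
      } else {
        stop("phenotype rows without genotypes: ", paste(extra, collapse = ", "))
      }
    }
    m <- match(gm$sample_ids, phen$sample_id)
    if (anyNA(m)) {
      stop("samples missing from phenotype table: ",
           paste(gm$sample_ids[is.na(m)], collapse = ", "))
    }
    phen <- phen[m, ]
    rownames(phen) <- NULL
  }
  phen
}

#' Read a SNP-to-gene override table
#'
#' TSV with columns `variant_id`, `gene_symbol`. Each row forces the
#' assignment of that variant to that gene regardless of genomic distance
#' (the mechanism used to keep a tag SNP in perfect LD with a causal
#' promoter variant attached to its gene).
#'
#' @param path path to the override TSV.
#' @return data.frame with columns `variant_id`, `gene_symbol`.
#' @export
read_overrides <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("variant_id", "gene_symbol")
  if (!all(req %in% names(tab))) {
    stop("override table needs columns: ", paste(req, collapse = ", "))
  }
  data.frame(variant_id = as.character(tab$variant_id),
             gene_symbol = as.character(tab$gene_symbol),
             stringsAsFactors = FALSE)
}
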