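## Readers and writers
##
## Tab-delimited tables with header rows; a minimal VCF 4.2 for variants
## (tumor allelic depths in the AD FORMAT field, region and annotation in
## INFO); truth as versioned JSON. Internal coordinates are 0-based half-open;
## VCF positions are 1-based and converted at this boundary.

#' Write a simulated dataset to a directory
#'
#' Emits `snps.tsv` (SNP allelic depths), `variants.tsv`, `variants.vcf`
#' (minimal VCF mirror of the variant table), `truth.json`, `arms.bed` and
#' `genes.bed` (BED-like 0-based half-open), readable back by the package
#' readers without loss.
#'
#' @param dataset `sim_dataset`
#' @param dir output directory (created if needed)
#' @return invisibly, the named file paths
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- c(snps = file.path(dir, "snps.tsv"),
             variants = file.path(dir, "variants.tsv"),
             vcf = file.path(dir, "variants.vcf"),
             truth = file.path(dir, "truth.json"),
             arms = file.path(dir, "arms.bed"),
             genes = file.path(dir, "genes.bed"))
  write_tsv(dataset$snps, paths["snps"])
  write_tsv(dataset$variants, paths["variants"])
  write_vcf_minimal(dataset$variants, dataset$genome, paths["vcf"])
  truth <- dataset$truth
  truth$schema_version <- "1.0"
  truth$seed <- dataset$seed
  jsonlite::write_json(truth_serializable(truth), paths["truth"],
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  at <- arm_table(dataset$genome)
  write_tsv(at[c("chrom", "start", "end", "arm")], paths["arms"],
            col.names = FALSE)
  gt <- dataset$genome$genes
  write_tsv(gt[c("chrom", "start", "end", "gene", "driver")], paths["genes"],
            col.names = FALSE)
  invisible(paths)
}

truth_serializable <- function(truth) {
  truth$scenario <- NULL   # closures-free already, but regions carry it too
  truth$regions <- lapply(truth$regions, function(r) r)
  truth
}

write_tsv <- function(x, path, col.names = TRUE) {
  ok <- try(utils::write.table(x, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = col.names),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write ", path, ": ", attr(ok, "condition")$message)
  invisible(path)
}

#' Read a tab-delimited table
#' @param path file path
#' @return data.frame
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = NA,
                         comment.char = "")
  if ("chrom" %in% names(x)) x$chrom <- as.character(x$chrom)
  x
}

#' Write a minimal VCF 4.2 from a variant table
#'
#' One record per (mutation, region): positions converted to 1-based, alt/ref
#' depths as the sample AD field (ref,alt order), region id / annotation
#' class / gene / driver in INFO.
#'
#' @param variants variant table (`id`, `chrom`, `pos`, `region`, `alt`,
#'   `ref`, `class`, optional `gene`, `driver`)
#' @param genome `genome_model` for contig headers
#' @param path output path
#' @return invisibly, `path`
#' @export
write_vcf_minimal <- function(variants, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=chromoevo",
           sprintf("##contig=<ID=%s,length=%d>", genome$chromosomes$chrom,
                   as.integer(genome$chromosomes$length)),
           '##INFO=<ID=RG,Number=1,Type=String,Description="Region id">',
           '##INFO=<ID=CLS,Number=1,Type=String,Description="Annotation class">',
           '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
           '##INFO=<ID=DRV,Number=1,Type=String,Description="Driver label">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "TUMOR"), collapse = "\t"))
  body <- character(0)
  if (nrow(variants)) {
    info <- paste0("RG=", variants$region, ";CLS=", variants$class,
                   ifelse(is.na(variants$gene %||% NA), "",
                          paste0(";GENE=", variants$gene)),
                   ifelse(is.na(variants$driver %||% NA), "",
                          paste0(";DRV=", variants$driver)))
    body <- paste(variants$chrom, as.integer(variants$pos) + 1L,
                  paste0(variants$id, "@", variants$region),
                  "A", "T", ".", "PASS", info, "AD",
                  paste0(variants$ref, ",", variants$alt), sep = "\t")
  }
  ok <- try(writeLines(c(hdr, body), path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write VCF: ", path)
  invisible(path)
}

#' Read a minimal VCF with allelic depths
#'
#' Positions are converted to the internal 0-based convention; alt/ref depths
#' are taken from the first sample's AD field. Records without a parseable AD
#' are rejected with their line number.
#'
#' @param path VCF path
#' @return variant table (`id`, `gene`, `chrom`, `pos`, `region`, `alt`,
#'   `ref`, `class`, `driver`)
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(id = character(0), gene = character(0),
                      chrom = character(0), pos = numeric(0),
                      region = character(0), alt = integer(0),
                      ref = integer(0), class = character(0),
                      driver = character(0), stringsAsFactors = FALSE))
  }
  gt <- v@gt
  fmt <- gt[, 1]
  ad_idx <- vapply(strsplit(fmt, ":"), function(f) match("AD", f), integer(1))
  ad_str <- mapply(function(cell, k) {
    if (is.na(k)) NA_character_ else strsplit(cell, ":")[[1]][k]
  }, gt[, 2], ad_idx)
  bad <- is.na(ad_str) | !grepl("^[0-9]+,[0-9]+$", ad_str)
  if (any(bad)) {
    stop("VCF record without parseable AD depths at data line ", which(bad)[1],
         " (", fix$CHROM[which(bad)[1]], ":", fix$POS[which(bad)[1]], ")")
  }
  ad <- do.call(rbind, strsplit(ad_str, ","))
  get_info <- function(key) {
    m <- regmatches(fix$INFO, regexec(paste0("(?:^|;)", key, "=([^;]*)"), fix$INFO))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  id_raw <- fix$ID
  data.frame(id = sub("@[^@]*$", "", id_raw),
             gene = get_info("GENE"),
             chrom = fix$CHROM, pos = as.numeric(fix$POS) - 1,
             region = get_info("RG"),
             alt = as.integer(ad[, 2]), ref = as.integer(ad[, 1]),
             class = get_info("CLS"), driver = get_info("DRV"),
             stringsAsFactors = FALSE)
}

#' Read a BED-like arm or gene table (0-based half-open)
#' @param path file path
#' @param what `"arms"` or `"genes"`
#' @return data.frame in the package's internal layout
#' @export
read_bed_table <- function(path, what = c("arms", "genes")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  x[[1]] <- as.character(x[[1]])
  if (what == "arms") {
    names(x) <- c("chrom", "start", "end", "arm")[seq_len(ncol(x))]
    x[c("arm", "chrom", "start", "end")]
  } else {
    names(x) <- c("chrom", "start", "end", "gene", "driver")[seq_len(ncol(x))]
    x$driver <- as.logical(x$driver)
    x[c("gene", "chrom", "start", "end", "driver")]
  }
}
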