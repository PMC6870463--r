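#' Write a genotype panel as VCF 4.2
#'
#' Emits a minimal VCF: contig headers, site quality, the consequence
#' label in `INFO/CSQ`, the gene in `INFO/GENE`, and per-sample `GT:GQ`
#' calls (hemizygous calls written as a single allele, absent W calls in
#' males as `.`).
#'
#' @param geno Long genotype tibble.
#' @param variants Variant table.
#' @param path Output file path (plain text).
#' @param sample_ids Column order; defaults to order of appearance.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(geno, variants, path, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(geno$sample)
  mats <- geno_long_to_matrices(geno, variants$variant_id, sample_ids)
  gq <- rep(99, length(sample_ids))
  contigs <- unique(variants$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sibxpress",
    paste0("##contig=<ID=", contigs, ">"),
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  gt_str <- function(a1, a2) {
    ifelse(is.na(a1), ".",
           ifelse(is.na(a2), as.character(a1), paste0(a1, "/", a2)))
  }
  rows <- vapply(seq_len(nrow(variants)), function(v) {
    calls <- paste0(gt_str(mats$a1[v, ], mats$a2[v, ]), ":99")
    info <- paste0("CSQ=", variants$consequence[v],
                   ifelse(is.na(variants$gene[v]), "",
                          paste0(";GENE=", variants$gene[v])))
    paste(c(variants$chrom[v], variants$pos[v], variants$variant_id[v],
            variants$ref[v], variants$alt[v], variants$qual[v], "PASS",
            info, "GT:GQ", calls), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a VCF into the long genotype panel representation
#'
#' Uses vcfR to parse VCF 4.x (gzipped accepted). Multi-allelic records
#' are split into biallelic records, one per alternative allele (genotypes
#' referring to another alt become missing). The consequence label is the
#' first-effect token of the INFO key named by `csq_key` when present.
#'
#' @param path VCF file.
#' @param csq_key INFO key holding the consequence annotation (first match
#'   among the given names is used).
#' @return A list: `variants` tibble and `geno` long tibble in the
#'   package's panel representation.
#' @export
read_panel_vcf <- function(path, csq_key = c("CSQ", "ANN")) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gq_raw <- suppressWarnings(vcfR::extract.gt(v, element = "GQ",
                                              as.numeric = TRUE))
  if (is.null(gq_raw)) gq_raw <- matrix(NA_real_, nrow(gt_raw),
                                        ncol(gt_raw))
  info <- vcfR::getINFO(v)
  csq <- rep(NA_character_, length(info))
  gene <- rep(NA_character_, length(info))
  for (key in csq_key) {
    hit <- is.na(csq) &
      stringr::str_detect(info, paste0("(^|;)", key, "="))
    csq[hit] <- stringr::str_match(info[hit],
                                   paste0(key, "=([^;|]+)"))[, 2]
  }
  ghit <- stringr::str_detect(info, "(^|;)GENE=")
  gene[ghit] <- stringr::str_match(info[ghit], "GENE=([^;]+)")[, 2]

  out_var <- list()
  out_geno <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      vid <- paste0(fix$CHROM[i], ":", fix$POS[i],
                    if (length(alts) > 1) paste0("_", ai) else "")
      gt <- gt_raw[i, ]
      parts <- stringr::str_split_fixed(gt, "[/|]", 2)
      to_code <- function(x) {
        out <- suppressWarnings(as.integer(x))
        # alleles other than this alt or ref are treated as missing
        out[!is.na(out) & out != 0L & out != ai] <- NA_integer_
        out[!is.na(out) & out == ai] <- 1L
        out
      }
      a1 <- to_code(parts[, 1])
      a2 <- to_code(parts[, 2])
      a2[parts[, 2] == ""] <- NA_integer_   # haploid call
      a1[is.na(a1)] <- NA_integer_
      # a diploid call with one unresolvable allele becomes fully missing
      bad <- parts[, 2] != "" & (is.na(a1) | is.na(a2))
      a1[bad] <- NA_integer_
      a2[bad] <- NA_integer_
      out_var[[length(out_var) + 1L]] <- tibble::tibble(
        variant_id = vid, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[ai],
        qual = suppressWarnings(as.numeric(fix$QUAL[i])),
        gene = gene[i], consequence = csq[i]
      )
      out_geno[[length(out_geno) + 1L]] <- tibble::tibble(
        variant_id = vid, sample = colnames(gt_raw),
        a1 = a1, a2 = a2, gq = unname(gq_raw[i, ])
      )
    }
  }
  list(variants = dplyr::bind_rows(out_var),
       geno = dplyr::bind_rows(out_geno))
}

#' Write / read the expression bundle as TSV
#'
#' The on-disk interchange: a genes-by-samples TPM matrix, a sample sheet
#' and a gene sheet, all tab-separated.
#'
#' @param expr,samples,genes The cohort tables.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or a list of the three tibbles (read).
#' @export
write_expression_bundle <- function(expr, samples, genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(expr, file.path(dir, "expression_tpm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression_bundle
#' @export
read_expression_bundle <- function(dir) {
  rd <- function(f) tibble::as_tibble(
    utils::read.delim(file.path(dir, f), check.names = FALSE,
                      stringsAsFactors = FALSE))
  list(expr = rd("expression_tpm.tsv"),
       samples = rd("samples.tsv"),
       genes = rd("genes.tsv"))
}

#' Export a correlation graph as an edge list
#'
#' @param graph A `correlation_graph`.
#' @param path Output TSV path (`node1`, `node2`, `r`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
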