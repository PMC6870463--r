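#' Build the F0 cross / F1 sibling-mating / F2 pedigree
#'
#' Constructs the breeding design: each F2 family descends from one
#' broiler x layer F0 pair whose F1 offspring include one male and one
#' female; that brother-sister pair produces the family's F2 birds. F2
#' sexes are assigned at random 1:1.
#'
#' @param config A [sim_config()].
#' @param founders Optional founder `individuals` tibble (as produced by
#'   [simulate_founders()]); generated from the config when omitted.
#' @return A tibble with class `c("pedigree", ...)`: `id`, `sex`,
#'   `generation` (0/1/2), `family` (letter label, `NA` for founders),
#'   `breed` (`NA` past F0), `sire`, `dam`.
#' @examples
#' ped <- build_pedigree(sim_config(n_f1_pairs = 3, n_f2_per_family = 4))
#' dplyr::count(ped, generation)
#' @export
build_pedigree <- function(config, founders = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(founders)) {
    nb <- config$n_founders_per_breed
    founders <- tibble::tibble(
      id = c(sprintf("F0_BR_%02d", seq_len(nb)),
             sprintf("F0_LA_%02d", seq_len(nb))),
      sex = rep(rep_len(c("M", "F"), nb), 2L),
      generation = 0L,
      family = NA_character_,
      breed = rep(c("broiler", "layer"), each = nb),
      sire = NA_character_,
      dam = NA_character_
    )
  }
  for (b in c("broiler", "layer")) {
    if (!any(founders$breed == b & founders$sex == "M") ||
        !any(founders$breed == b & founders$sex == "F")) {
      stop("need at least one founder of each sex in breed ", b,
           call. = FALSE)
    }
  }
  set.seed(stage_seed(config, "pedigree"))

  fam_labels <- family_labels(config$n_f1_pairs)
  br_m <- founders$id[founders$breed == "broiler" & founders$sex == "M"]
  br_f <- founders$id[founders$breed == "broiler" & founders$sex == "F"]
  la_m <- founders$id[founders$breed == "layer" & founders$sex == "M"]
  la_f <- founders$id[founders$breed == "layer" & founders$sex == "F"]

  f1 <- purrr::map_dfr(seq_len(config$n_f1_pairs), function(i) {
    # alternate cross direction so both reciprocal crosses occur
    if (i %% 2L == 1L) {
      sire <- sample(br_m, 1L); dam <- sample(la_f, 1L)
    } else {
      sire <- sample(la_m, 1L); dam <- sample(br_f, 1L)
    }
    tibble::tibble(
      id = sprintf("F1_%s_%s", fam_labels[i], c("M", "F")),
      sex = c("M", "F"),
      generation = 1L,
      family = fam_labels[i],
      breed = NA_character_,
      sire = sire,
      dam = dam
    )
  })

  f2 <- purrr::map_dfr(seq_len(config$n_f1_pairs), function(i) {
    n <- config$n_f2_per_family[i]
    if (n == 0L) return(NULL)
    tibble::tibble(
      id = sprintf("F2_%s_%02d", fam_labels[i], seq_len(n)),
      sex = sample(c("M", "F"), n, replace = TRUE),
      generation = 2L,
      family = fam_labels[i],
      breed = NA_character_,
      sire = sprintf("F1_%s_M", fam_labels[i]),
      dam = sprintf("F1_%s_F", fam_labels[i])
    )
  })

  ped <- dplyr::bind_rows(founders, f1, f2)
  class(ped) <- c("pedigree", class(ped))
  ped
}

family_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else sprintf("FAM%03d", seq_len(n))
}

#' Drop alleles through a pedigree under Mendelian transmission
#'
#' Simulates transmission of founder alleles to every descendant: one allele
#' per autosomal locus from each parent, chosen uniformly among that
#' parent's two; sons receive one Z from each parent, daughters their
#' father's Z (and the mother's W at W loci); genotype calls carry no
#' missingness beyond the structural hemizygosity of Z/W loci.
#'
#' @param pedigree A pedigree tibble from [build_pedigree()] (or any tibble
#'   with `id`, `sex`, `generation`, `sire`, `dam`).
#' @param founders A `founder_sim` object or a list with `variants` and
#'   `geno` covering every founder at every locus.
#' @param seed Integer seed for the transmission draws.
#' @return A long genotype tibble (`variant_id`, `sample`, `a1`, `a2`,
#'   `gq`) covering every individual in the pedigree.
#' @examples
#' cfg <- sim_config(n_autosomal_genes = 10, n_z_genes = 2, n_w_genes = 1,
#'                   n_neutral_variants = 5, n_f1_pairs = 2,
#'                   n_f2_per_family = 3, trans_module_size = 2,
#'                   mesenchyme_module_size = 2, n_lps_induced = 2,
#'                   n_lps_repressed = 2, seed = 3)
#' fs <- simulate_founders(cfg)
#' ped <- build_pedigree(cfg, fs$individuals)
#' g <- gene_drop(ped, fs, seed = 3)
#' nrow(g) == nrow(fs$variants) * nrow(ped)
#' @export
gene_drop <- function(pedigree, founders, seed = 1L) {
  variants <- founders$variants
  founder_geno <- founders$geno
  founder_ids <- unique(founder_geno$sample)

  unknown <- setdiff(stats::na.omit(c(pedigree$sire, pedigree$dam)),
                     pedigree$id)
  if (length(unknown) > 0) {
    stop("pedigree refers to unknown individual(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  roots <- pedigree$id[is.na(pedigree$sire) & is.na(pedigree$dam)]
  if (!all(roots %in% founder_ids)) {
    stop("founder(s) without genotypes: ",
         paste(utils::head(setdiff(roots, founder_ids), 5), collapse = ", "),
         call. = FALSE)
  }

  set.seed(as.integer(seed))
  mats <- drop_alleles(pedigree, variants,
                       geno_long_to_matrices(founder_geno,
                                             variants$variant_id,
                                             founder_ids))
  out <- geno_matrices_to_long(mats$a1, mats$a2, gq = 99)
  out[out$sample %in% pedigree$id, ]
}

# Vectorized transmission: children of each generation are processed in one
# shot with row masks for Z/W loci. A parent's transmitted allele is a
# uniform pick among its two alleles; hemizygous loci transmit the single
# stored allele deterministically.
drop_alleles <- function(pedigree, variants, founder_mats) {
  n_var <- nrow(variants)
  is_z <- variants$chrom == "chrZ"
  is_w <- variants$chrom == "chrW"
  ids <- pedigree$id
  n_ind <- length(ids)
  a1 <- matrix(NA_integer_, n_var, n_ind,
               dimnames = list(variants$variant_id, ids))
  a2 <- a1
  fcols <- match(colnames(founder_mats$a1), ids)
  ok <- !is.na(fcols)
  a1[, fcols[ok]] <- founder_mats$a1[, ok]
  a2[, fcols[ok]] <- founder_mats$a2[, ok]

  transmit <- function(parent_idx) {
    p1 <- a1[, parent_idx, drop = FALSE]
    p2 <- a2[, parent_idx, drop = FALSE]
    pick2 <- matrix(stats::runif(length(p1)) < 0.5, nrow(p1))
    out <- p1
    use2 <- pick2 & !is.na(p2)
    out[use2] <- p2[use2]
    out
  }

  for (g in sort(unique(pedigree$generation[!is.na(pedigree$sire)]))) {
    child <- which(pedigree$generation == g & !is.na(pedigree$sire))
    if (length(child) == 0) next
    si <- match(pedigree$sire[child], ids)
    di <- match(pedigree$dam[child], ids)
    pat <- transmit(si)   # paternal gamete (no W rows: NA there)
    mat <- transmit(di)   # maternal gamete (Z or W depending on row)
    c_a1 <- pat
    c_a2 <- mat
    male <- pedigree$sex[child] == "M"
    # daughters: single paternal Z, maternal W; no maternal Z
    c_a2[is_z, !male] <- NA_integer_
    c_a1[is_w, ] <- NA_integer_
    c_a1[is_w, !male] <- mat[is_w, !male, drop = FALSE]
    c_a2[is_w, ] <- NA_integer_
    # sons never carry W (maternal gamete at W rows discarded)
    c_a2[is_w, male] <- NA_integer_
    a1[, child] <- c_a1
    a2[, child] <- c_a2
  }
  list(a1 = a1, a2 = a2)
}
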