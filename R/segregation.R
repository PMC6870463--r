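#' Exact F2 genotype probabilities for the F0 cross / F1 sibling design
#'
#' Enumerates, for a single autosomal biallelic locus, the genotype
#' distribution of a random F2 bird whose parents are a randomly chosen F1
#' brother-sister pair (drawn without genotype selection) from a cross of
#' the two given F0 founders. All probabilities are exact dyadic rationals
#' obtained by summing over the 3 x 3 F1 genotype pairs weighted by their
#' independent Mendelian probabilities.
#'
#' The two design expectations fall straight out: a null allele
#' heterozygous in one grandparent (`c("het", "hom_ref")`) gives
#' P(F2 hom-alt) = 1/16, and fully divergent grandparents
#' (`c("hom_alt", "hom_ref")`) make every F1 a heterozygote so
#' P(F2 hom-alt) = 1/4.
#'
#' @param f0 Character vector of length 2: genotypes of the two F0 parents,
#'   each of `"hom_ref"`, `"het"`, `"hom_alt"`.
#' @param chromosome `"autosome"` (default) or `"Z"`. For Z loci the result
#'   is sex-stratified: male F2 genotype triple plus female hemizygous
#'   allele probabilities, with the F0 cross read as (male ZZ genotype,
#'   female single-Z allele where `"het"` is not allowed for the female).
#' @return For autosomes, a tibble with `genotype`
#'   (`hom_alt`/`het`/`hom_ref`) and exact `prob` (sums to 1). For Z, a
#'   list of two such tibbles (`male`, `female`), the female one over the
#'   single-allele states `alt`/`ref`.
#' @examples
#' f2_genotype_probs(c("het", "hom_ref"))       # 1/16 hom-alt
#' f2_genotype_probs(c("hom_alt", "hom_ref"))   # 1/4 hom-alt
#' @export
f2_genotype_probs <- function(f0, chromosome = c("autosome", "Z")) {
  chromosome <- match.arg(chromosome)
  geno_levels <- c("hom_alt", "het", "hom_ref")
  if (length(f0) != 2L || !all(f0 %in% geno_levels)) {
    stop("`f0` must be two genotypes from ",
         paste(geno_levels, collapse = ", "), call. = FALSE)
  }
  if (chromosome == "autosome") {
    f1_dist <- cross_offspring_dist(f0[1], f0[2])
    # F1 sire and dam are independent draws from the F1 distribution
    probs <- c(hom_alt = 0, het = 0, hom_ref = 0)
    for (gs in geno_levels) for (gd in geno_levels) {
      w <- f1_dist[gs] * f1_dist[gd]
      if (w > 0) probs <- probs + w * cross_offspring_dist(gs, gd)
    }
    return(tibble::tibble(genotype = geno_levels,
                          prob = unname(probs[geno_levels])))
  }
  z_f2_probs(f0)
}

# offspring genotype distribution of one autosomal diploid x diploid cross
cross_offspring_dist <- function(g1, g2) {
  gam <- function(g) switch(g,
    hom_alt = c(alt = 1, ref = 0),
    het     = c(alt = 0.5, ref = 0.5),
    hom_ref = c(alt = 0, ref = 1))
  p1 <- gam(g1); p2 <- gam(g2)
  c(hom_alt = p1["alt"] * p2["alt"],
    het     = p1["alt"] * p2["ref"] + p1["ref"] * p2["alt"],
    hom_ref = p1["ref"] * p2["ref"]) |> stats::setNames(
      c("hom_alt", "het", "hom_ref"))
}

# Z locus: F0 = (male ZZ genotype, female single-Z allele). F1 sons are ZZ,
# daughters hemizygous; a random F1 sibling pair then yields sex-stratified
# F2 distributions.
z_f2_probs <- function(f0) {
  male_g <- f0[1]
  fem_allele <- switch(f0[2], hom_alt = c(alt = 1), hom_ref = c(ref = 1),
                       het = stop("a female is hemizygous at a Z locus; ",
                                  "use 'hom_alt' or 'hom_ref' for her ",
                                  "single allele", call. = FALSE))
  pat <- switch(male_g, hom_alt = c(alt = 1, ref = 0),
                het = c(alt = 0.5, ref = 0.5),
                hom_ref = c(alt = 0, ref = 1))
  mat <- c(alt = 0, ref = 0)
  mat[names(fem_allele)] <- fem_allele
  # F1 son genotype: paternal Z x maternal Z; F1 daughter allele: paternal Z
  son <- c(hom_alt = pat["alt"] * mat["alt"],
           het = pat["alt"] * mat["ref"] + pat["ref"] * mat["alt"],
           hom_ref = pat["ref"] * mat["ref"])
  names(son) <- c("hom_alt", "het", "hom_ref")
  daughter <- pat  # single paternal Z allele
  m_probs <- c(hom_alt = 0, het = 0, hom_ref = 0)
  f_probs <- c(alt = 0, ref = 0)
  for (gs in names(son)) for (al in names(daughter)) {
    w <- son[gs] * daughter[al]
    if (w == 0) next
    sire_gam <- switch(gs, hom_alt = c(alt = 1, ref = 0),
                       het = c(alt = 0.5, ref = 0.5),
                       hom_ref = c(alt = 0, ref = 1))
    dam_al <- c(alt = as.numeric(al == "alt"), ref = as.numeric(al == "ref"))
    off <- c(
      hom_alt = unname(sire_gam["alt"] * dam_al["alt"]),
      het = unname(sire_gam["alt"] * dam_al["ref"] +
                     sire_gam["ref"] * dam_al["alt"]),
      hom_ref = unname(sire_gam["ref"] * dam_al["ref"]))
    m_probs <- m_probs + w * off
    f_probs <- f_probs + w * sire_gam
  }
  list(male = tibble::tibble(genotype = names(m_probs),
                             prob = unname(m_probs)),
       female = tibble::tibble(allele = names(f_probs),
                               prob = unname(f_probs)))
}

#' Monte-Carlo twin of the analytic F2 expectations
#'
#' Re-derives the F2 genotype frequencies by explicit gene-drop simulation:
#' each replicate creates an independent F1 brother-sister pair from the
#' given F0 cross and one F2 offspring, reusing the package's transmission
#' engine on a single-locus panel.
#'
#' @param f0 As in [f2_genotype_probs()] (autosomal).
#' @param n_replicates Number of independent F2 birds to simulate.
#' @param seed Integer seed.
#' @return A tibble: `genotype`, `expected` (analytic), `freq` (empirical),
#'   `se` (binomial standard error), `n`.
#' @examples
#' simulate_f2_genotype_freqs(c("het", "hom_ref"), 5000, seed = 2)
#' @export
simulate_f2_genotype_freqs <- function(f0, n_replicates = 10000L,
                                       seed = 1L) {
  stopifnot(n_replicates >= 1)
  analytic <- f2_genotype_probs(f0)
  n <- as.integer(n_replicates)

  founders <- tibble::tibble(
    id = c("P1", "P2"), sex = c("M", "F"), generation = 0L,
    family = NA_character_, breed = c("broiler", "layer"),
    sire = NA_character_, dam = NA_character_
  )
  fam <- sprintf("R%06d", seq_len(n))
  ped <- dplyr::bind_rows(
    founders,
    tibble::tibble(id = paste0("F1M_", fam), sex = "M", generation = 1L,
                   family = fam, breed = NA, sire = "P1", dam = "P2"),
    tibble::tibble(id = paste0("F1F_", fam), sex = "F", generation = 1L,
                   family = fam, breed = NA, sire = "P1", dam = "P2"),
    tibble::tibble(id = paste0("F2_", fam), sex = "M", generation = 2L,
                   family = fam, breed = NA,
                   sire = paste0("F1M_", fam), dam = paste0("F1F_", fam))
  )
  alleles <- function(g) switch(g, hom_alt = c(1L, 1L), het = c(1L, 0L),
                                hom_ref = c(0L, 0L))
  variants <- tibble::tibble(variant_id = "chr1:1", chrom = "chr1",
                             pos = 1L, ref = "A", alt = "T", qual = 999,
                             gene = NA_character_, consequence = "other")
  g1 <- alleles(f0[1]); g2 <- alleles(f0[2])
  founder_geno <- tibble::tibble(
    variant_id = "chr1:1", sample = c("P1", "P2"),
    a1 = c(g1[1], g2[1]), a2 = c(g1[2], g2[2]), gq = 99
  )
  drop <- gene_drop(ped, list(variants = variants, geno = founder_geno),
                    seed = seed)
  f2 <- drop[startsWith(drop$sample, "F2_"), ]
  dos <- f2$a1 + f2$a2
  counts <- c(hom_alt = sum(dos == 2L), het = sum(dos == 1L),
              hom_ref = sum(dos == 0L))
  freq <- counts / n
  tibble::tibble(
    genotype = analytic$genotype,
    expected = analytic$prob,
    freq = unname(freq[analytic$genotype]),
    se = sqrt(analytic$prob * (1 - analytic$prob) / n),
    n = n
  )
}

#' Select F1 sibling pairs heterozygous at all loci of interest
#'
#' Mirrors the real design step of genotyping F1 birds and mating only
#' brother-sister pairs in which both members are heterozygous at every
#' listed locus.
#'
#' @param geno Long genotype tibble covering the F1 individuals.
#' @param pedigree Pedigree tibble identifying F1 individuals and their
#'   parents (a sibling pair shares both parents).
#' @param loci Character vector of `variant_id`s that must all be
#'   heterozygous.
#' @return A tibble of qualifying pairs: `family`, `male`, `female`
#'   (possibly empty).
#' @export
select_f1_pairs <- function(geno, pedigree, loci) {
  missing <- setdiff(loci, unique(geno$variant_id))
  if (length(missing) > 0) {
    stop("locus absent from panel: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  f1 <- pedigree[pedigree$generation == 1L, ]
  het_at_all <- geno |>
    dplyr::filter(.data$variant_id %in% loci,
                  .data$sample %in% f1$id) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(ok = all(!is.na(.data$a1) & !is.na(.data$a2) &
                                .data$a1 + .data$a2 == 1L),
                     n_loci = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$ok, .data$n_loci == length(loci))
  hets <- het_at_all$sample
  males <- f1[f1$sex == "M" & f1$id %in% hets, ]
  females <- f1[f1$sex == "F" & f1$id %in% hets, ]
  pairs <- dplyr::inner_join(
    males[, c("id", "sire", "dam", "family")],
    females[, c("id", "sire", "dam", "family")],
    by = c("sire", "dam"), suffix = c("_m", "_f"),
    relationship = "many-to-many"
  )
  tibble::tibble(family = pairs$family_m, male = pairs$id_m,
                 female = pairs$id_f)
}
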