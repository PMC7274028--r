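# Synthetic fixture generator: coherent VCF + FASTA + GFF3 + metadata sets
# with planted structure (haplotype classes, allele frequencies, effect
# variants, geographic clusters) and machine-readable truth tables, so the
# whole toolchain is testable without any external dataset.
#
# The planted world is simple by design: haplotype classes are hard
# genotype assignments with independent per-call noise/het/missing flips,
# sites are unlinked, and geography is Gaussian scatter around cluster
# centres. That is enough to exercise every filter and analysis; it does
# not emulate LD, coalescent structure, or real error profiles.

#' Describe a synthetic fixture
#'
#' Defaults describe a small but fully featured panel: one 20 kb plus one
#' 6 kb contig, 24 samples in two groups, 200 random variant sites (10%
#' indels), 3 planted haplotype classes with 30% per-site divergence, 2%
#' genotype noise, 5% heterozygous and 5% missing calls, and three
#' geographic clusters with 100 km spread.
#'
#' @param seed RNG seed for the whole fixture
#' @param contigs named integer vector of contig lengths
#' @param n_samples number of samples
#' @param n_sites number of random variant sites
#' @param groups named integer vector of group sizes (must sum to
#'   `n_samples`)
#' @param planted_haplotypes list `count`, `divergence` (per-site
#'   probability that a class carries the ALT allele)
#' @param site_freqs optional per-site ALT allele frequencies; when given,
#'   alleles are drawn iid Bernoulli per allele instead of by haplotype
#'   class (used for frequency-recovery checks)
#' @param indel_fraction fraction of random sites that are indels
#' @param het_rate per-call probability of turning a call heterozygous
#' @param noise_rate per-call probability of flipping the planted allele
#' @param missing_rate per-call probability of a missing call
#' @param geo_clusters data.frame `lat`, `lon`, `spread_km`
#' @param plant_effects also plant one variant of every effect class
#'   inside/around the generated gene models
#' @param with_ann write SnpEff-style ANN INFO entries for planted effect
#'   variants
#' @param index write bgzipped + tabix-indexed VCF and FASTA .fai alongside
#'   the plain-text files
#' @return a `fixture_spec` list
#' @export
fixture_spec <- function(seed = 1L,
                         contigs = c(`1A` = 20000L, `2B` = 6000L),
                         n_samples = 24L, n_sites = 200L,
                         groups = NULL,
                         planted_haplotypes = list(count = 3L, divergence = 0.3),
                         site_freqs = NULL,
                         indel_fraction = 0.1,
                         het_rate = 0.05, noise_rate = 0.02, missing_rate = 0.05,
                         geo_clusters = data.frame(
                           lat = c(35, 48, -10), lon = c(105, 15, -55),
                           spread_km = c(100, 100, 100)),
                         plant_effects = TRUE, with_ann = FALSE, index = TRUE) {
  if (is.null(groups)) {
    groups <- c(grpA = ceiling(n_samples / 2), grpB = floor(n_samples / 2))
  }
  if (sum(groups) != n_samples)
    ss_stop("parameter", "group sizes must sum to n_samples")
  for (r in c(indel_fraction, het_rate, noise_rate, missing_rate))
    if (r < 0 || r > 1) ss_stop("parameter", "rates must lie in [0, 1]")
  structure(list(seed = as.integer(seed), contigs = contigs,
                 n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
                 groups = groups, planted_haplotypes = planted_haplotypes,
                 site_freqs = site_freqs, indel_fraction = indel_fraction,
                 het_rate = het_rate, noise_rate = noise_rate,
                 missing_rate = missing_rate, geo_clusters = geo_clusters,
                 plant_effects = isTRUE(plant_effects), with_ann = isTRUE(with_ann),
                 index = isTRUE(index)),
            class = "fixture_spec")
}

# two multi-exon genes (one per strand) placed on the first contig;
# CDS phases follow the GFF3 convention (bases to skip to the next codon)
fixture_genes <- function(contig, L) {
  stopifnot(L >= 4000L)
  mk <- function(gid, tid, start, strand) {
    ex <- data.frame(start = c(start, start + 300L),
                     end = c(start + 239L, start + 599L))
    cds <- data.frame(start = c(start + 60L, start + 300L),
                      end = c(start + 239L, start + 500L))
    lens <- cds$end - cds$start + 1L
    phases <- integer(2L)
    if (strand == "+") {
      phases[2L] <- (3L - (lens[1L] %% 3L)) %% 3L
    } else {
      phases[1L] <- (3L - (lens[2L] %% 3L)) %% 3L
    }
    list(geneId = gid, transcriptId = tid, chrom = contig, strand = strand,
         span = c(start, start + 599L), exons = ex,
         cds = data.frame(start = cds$start, end = cds$end, phase = phases))
  }
  list(mk("gene1", "gene1.t1", as.integer(round(L * 0.10)), "+"),
       mk("gene2", "gene2.t1", as.integer(round(L * 0.45)), "-"))
}

write_fixture_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    at <- function(...) paste(..., sep = "\t")
    lines <- c(lines,
      at(g$chrom, "snpscope", "gene", g$span[1L], g$span[2L], ".", g$strand, ".",
         paste0("ID=", g$geneId)),
      at(g$chrom, "snpscope", "mRNA", g$span[1L], g$span[2L], ".", g$strand, ".",
         paste0("ID=", g$transcriptId, ";Parent=", g$geneId)))
    for (i in seq_len(nrow(g$exons)))
      lines <- c(lines, at(g$chrom, "snpscope", "exon", g$exons$start[i],
                           g$exons$end[i], ".", g$strand, ".",
                           paste0("Parent=", g$transcriptId)))
    for (i in seq_len(nrow(g$cds)))
      lines <- c(lines, at(g$chrom, "snpscope", "CDS", g$cds$start[i],
                           g$cds$end[i], ".", g$strand, g$cds$phase[i],
                           paste0("ID=", g$geneId, ".cds;Parent=", g$transcriptId)))
  }
  writeLines(lines, path)
}

# search the CDS of `gene` for single-base substitutions of each coding
# effect; returns planted records with their intended classes
plant_effect_variants <- function(genes, refseq) {
  gene <- genes[[1L]]  # plus-strand gene: easiest to reason about
  frame <- coding_frame(gene)
  fetch <- function(chrom, s, e) substr(refseq, s, e)
  found <- list()
  want <- c("synonymous", "missense", "stop_gained")
  for (cpos in seq_len(frame$total)) {
    if (!length(want)) break
    gp <- genomic_pos(frame, gene$strand, cpos)
    ref <- substr(refseq, gp, gp)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      a <- annotate_one_transcript(gene$chrom, gp, ref, alt, gene, fetch)
      if (!is.null(a) && a$effectClass %in% want) {
        found[[a$effectClass]] <- list(chrom = gene$chrom, pos = gp, ref = ref,
                                       alt = alt, class = a$effectClass)
        want <- setdiff(want, a$effectClass)
        break
      }
    }
  }
  if (length(want))
    ss_stop("spec", sprintf("gene too short to plant: %s", paste(want, collapse = ", ")))
  # frameshift: 1-bp insertion mid-CDS
  fp <- gene$cds$start[1L] + 5L
  found$frameshift <- list(chrom = gene$chrom, pos = fp,
                           ref = substr(refseq, fp, fp),
                           alt = paste0(substr(refseq, fp, fp), "A"),
                           class = "frameshift")
  # splice region: first intronic base after exon 1
  sp <- gene$exons$end[1L] + 1L
  found$splice_region <- list(chrom = gene$chrom, pos = sp,
                              ref = substr(refseq, sp, sp),
                              alt = setdiff(c("A", "C", "G", "T"),
                                            substr(refseq, sp, sp))[1L],
                              class = "splice_region")
  # deep intron: midway between the exons
  ip <- as.integer((gene$exons$end[1L] + gene$exons$start[2L]) / 2)
  found$intron <- list(chrom = gene$chrom, pos = ip,
                       ref = substr(refseq, ip, ip),
                       alt = setdiff(c("A", "C", "G", "T"), substr(refseq, ip, ip))[1L],
                       class = "intron")
  # intergenic: far downstream of the last gene
  gp2 <- genes[[length(genes)]]$span[2L] + 500L
  found$intergenic <- list(chrom = gene$chrom, pos = gp2,
                           ref = substr(refseq, gp2, gp2),
                           alt = setdiff(c("A", "C", "G", "T"), substr(refseq, gp2, gp2))[1L],
                           class = "intergenic")
  found
}

fixture_vcf_header <- function(contigs, with_ann) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    if (with_ann)
      "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: Allele|Annotation|Impact|Gene_Name|Gene_ID|Feature_Type|Feature_ID|Transcript_BioType|Rank|HGVS.c|HGVS.p\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
}

#' Generate a complete synthetic fixture
#'
#' Writes, under `out_dir`: `reference.fa` (plus `.fai` when `index`),
#' `annotation.gff3`, `variants.vcf` (plus bgzipped + tabix-indexed copy
#' when `index`), `samples.tsv`, `groups.tsv`, and the truth tables
#' `truth_sites.tsv` (per-site planted type, frequency and effect class)
#' and `truth_samples.tsv` (haplotype class, geographic cluster, group per
#' sample). Identical spec + seed gives byte-identical text outputs.
#'
#' @param spec a [fixture_spec()]
#' @param out_dir output directory (created if needed)
#' @return list with `paths` (named), `spec`, and the truth tables
#' @export
generate_fixture <- function(spec, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    ss_stop("io", sprintf("cannot create output directory '%s'", out_dir))
  set.seed(spec$seed)
  contigs <- spec$contigs
  seqs <- lapply(contigs, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))

  # --- gene models on the first contig
  genes <- fixture_genes(names(contigs)[[1L]], contigs[[1L]])
  gff_path <- file.path(out_dir, "annotation.gff3")
  write_fixture_gff3(genes, gff_path)

  # --- planted effect variants (before random sites, so spans can be avoided)
  effects <- if (spec$plant_effects) plant_effect_variants(genes, seqs[[1L]]) else list()
  eff_df <- if (length(effects)) do.call(rbind, lapply(effects, function(e)
    data.frame(chrom = e$chrom, pos = e$pos, ref = e$ref, alt = e$alt,
               class = e$class, stringsAsFactors = FALSE))) else NULL

  # --- random site positions, spread over contigs by length, min 12 bp apart
  n_per <- round(spec$n_sites * contigs / sum(contigs))
  n_per[1L] <- spec$n_sites - sum(n_per[-1L])
  site_list <- list()
  for (ci in seq_along(contigs)) {
    cname <- names(contigs)[[ci]]
    avoid <- if (!is.null(eff_df)) eff_df$pos[eff_df$chrom == cname] else integer(0)
    cand <- setdiff(seq.int(10L, contigs[[ci]] - 10L, by = 12L),
                    unlist(lapply(avoid, function(p) (p - 12L):(p + 12L))))
    pos <- sort(sample(cand, min(n_per[[ci]], length(cand))))
    if (length(pos))
      site_list[[cname]] <- data.frame(chrom = cname, pos = pos,
                                       stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  ns <- nrow(sites)

  # --- alleles
  sites$ref <- sites$alt <- character(ns)
  sites$type <- "snp"
  is_indel <- runif(ns) < spec$indel_fraction
  for (i in seq_len(ns)) {
    sq <- seqs[[sites$chrom[[i]]]]
    base <- substr(sq, sites$pos[[i]], sites$pos[[i]])
    if (is_indel[[i]] && runif(1) < 0.5) {           # insertion
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1L), replace = TRUE),
                   collapse = "")
      sites$ref[[i]] <- base; sites$alt[[i]] <- paste0(base, ins)
      sites$type[[i]] <- "ins"
    } else if (is_indel[[i]]) {                      # deletion
      d <- sample(1:3, 1L)
      sites$ref[[i]] <- substr(sq, sites$pos[[i]], sites$pos[[i]] + d)
      sites$alt[[i]] <- base
      sites$type[[i]] <- "del"
    } else {
      sites$ref[[i]] <- base
      sites$alt[[i]] <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    }
  }

  # --- samples, groups, geography
  n <- spec$n_samples
  acc <- sprintf("S%02d", seq_len(n))
  vcf_id <- sprintf("smp%02d_lib1", seq_len(n))
  disp <- sprintf("Line %02d", seq_len(n))
  group_of <- rep(names(spec$groups), spec$groups)
  ncl <- nrow(spec$geo_clusters)
  cluster_of <- rep_len(seq_len(ncl), n)
  lat <- spec$geo_clusters$lat[cluster_of] +
    rnorm(n, 0, spec$geo_clusters$spread_km[cluster_of] / 111)
  lon <- spec$geo_clusters$lon[cluster_of] +
    rnorm(n, 0, spec$geo_clusters$spread_km[cluster_of] / 111)
  lat <- pmax(-89.9, pmin(89.9, lat))

  # --- planted genotypes
  k <- spec$planted_haplotypes$count
  class_of <- rep_len(seq_len(k), n)
  iid_mode <- !is.null(spec$site_freqs)
  if (iid_mode) {
    p <- rep_len(spec$site_freqs, ns)
    a1 <- matrix(rbinom(ns * n, 1L, rep(p, n)), ns, n)
    a2 <- matrix(rbinom(ns * n, 1L, rep(p, n)), ns, n)
    planted_freq <- p
  } else {
    class_allele <- matrix(rbinom(ns * k, 1L, spec$planted_haplotypes$divergence), ns, k)
    for (j in seq_len(min(k, ns))) {   # force pairwise-distinct class signatures
      class_allele[j, ] <- 0L; class_allele[j, j] <- 1L
    }
    a1 <- a2 <- class_allele[, class_of, drop = FALSE]
    flip <- matrix(runif(ns * n) < spec$noise_rate, ns, n)
    a1[flip] <- 1L - a1[flip]; a2[flip] <- a1[flip]
    het <- matrix(runif(ns * n) < spec$het_rate, ns, n)
    a1[het] <- 0L; a2[het] <- 1L
    planted_freq <- rowMeans(class_allele[, class_of, drop = FALSE])
  }
  miss <- matrix(runif(ns * n) < spec$missing_rate, ns, n)

  # --- planted effect-variant genotypes: clean 50/50 hom split
  if (!is.null(eff_df)) {
    ne <- nrow(eff_df)
    ea <- matrix(0L, ne, n)
    ea[, seq_len(ceiling(n / 2))] <- 1L
    all_sites <- rbind(
      data.frame(sites[, c("chrom", "pos", "ref", "alt", "type")],
                 planted_freq = planted_freq, effect = NA_character_),
      data.frame(chrom = eff_df$chrom, pos = eff_df$pos, ref = eff_df$ref,
                 alt = eff_df$alt, type = "effect",
                 planted_freq = rowMeans(ea), effect = eff_df$class))
    a1 <- rbind(a1, ea); a2 <- rbind(a2, ea)
    miss <- rbind(miss, matrix(FALSE, ne, n))
  } else {
    all_sites <- data.frame(sites[, c("chrom", "pos", "ref", "alt", "type")],
                            planted_freq = planted_freq, effect = NA_character_)
  }
  ord <- order(match(all_sites$chrom, names(contigs)), all_sites$pos)
  all_sites <- all_sites[ord, , drop = FALSE]
  a1 <- a1[ord, , drop = FALSE]; a2 <- a2[ord, , drop = FALSE]
  miss <- miss[ord, , drop = FALSE]
  rownames(all_sites) <- NULL
  nt <- nrow(all_sites)

  # --- VCF
  dp <- matrix(rpois(nt * n, 20L) + 1L, nt, n)
  gq <- matrix(sample(30:99, nt * n, replace = TRUE), nt, n)
  recs <- vapply(seq_len(nt), function(i) {
    cells <- vapply(seq_len(n), function(s) {
      if (miss[i, s]) "./.:.:." else
        sprintf("%d/%d:%d:%d", a1[i, s], a2[i, s], dp[i, s], gq[i, s])
    }, character(1))
    info <- "."
    if (spec$with_ann && !is.na(all_sites$effect[[i]])) {
      term <- c(missense = "missense_variant", synonymous = "synonymous_variant",
                stop_gained = "stop_gained", frameshift = "frameshift_variant",
                splice_region = "splice_region_variant", intron = "intron_variant",
                intergenic = "intergenic_region")[[all_sites$effect[[i]]]]
      info <- sprintf("ANN=%s|%s|MODERATE|gene1|gene1|transcript|gene1.t1|protein_coding|1|n.%d%s>%s",
                      all_sites$alt[[i]], term, all_sites$pos[[i]],
                      all_sites$ref[[i]], all_sites$alt[[i]])
    }
    paste(c(all_sites$chrom[[i]], all_sites$pos[[i]], ".", all_sites$ref[[i]],
            all_sites$alt[[i]], "50", "PASS", info, "GT:DP:GQ", cells),
          collapse = "\t")
  }, character(1))
  vcf_path <- file.path(out_dir, "variants.vcf")
  writeLines(c(fixture_vcf_header(contigs, spec$with_ann),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vcf_id), collapse = "\t"),
               recs), vcf_path)

  # --- FASTA
  fasta_path <- file.path(out_dir, "reference.fa")
  fa_lines <- unlist(lapply(names(contigs), function(cn)
    c(paste0(">", cn), wrap_seq(seqs[[cn]]))))
  writeLines(fa_lines, fasta_path)

  # --- metadata
  samples_path <- file.path(out_dir, "samples.tsv")
  sm <- data.frame(vcfID = vcf_id, accessionName = acc, displayName = disp,
                   origin = paste0("cluster", cluster_of),
                   latitude = sprintf("%.5f", lat),
                   longitude = sprintf("%.5f", lon),
                   stringsAsFactors = FALSE)
  write.table(sm, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  groups_path <- file.path(out_dir, "groups.tsv")
  writeLines(vapply(names(spec$groups), function(g)
    paste0(g, "\t", paste(acc[group_of == g], collapse = ",")), character(1)),
    groups_path)

  # --- truth tables
  truth_sites_path <- file.path(out_dir, "truth_sites.tsv")
  write.table(all_sites, truth_sites_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_samples_path <- file.path(out_dir, "truth_samples.tsv")
  truth_samples <- data.frame(accessionName = acc, vcfID = vcf_id,
                              haplotypeClass = if (iid_mode) NA_integer_ else class_of,
                              group = group_of, cluster = cluster_of,
                              stringsAsFactors = FALSE)
  write.table(truth_samples, truth_samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  paths <- list(vcf = vcf_path, fasta = fasta_path, gff = gff_path,
                samples = samples_path, groups = groups_path,
                truth_sites = truth_sites_path, truth_samples = truth_samples_path)
  if (spec$index) {
    paths$vcf_gz <- Rsamtools::bgzip(vcf_path, dest = paste0(vcf_path, ".gz"),
                                     overwrite = TRUE)
    Rsamtools::indexTabix(paths$vcf_gz, format = "vcf")
    Rsamtools::indexFa(fasta_path)
  }
  list(paths = paths, spec = spec, truth_sites = all_sites,
       truth_samples = truth_samples)
}
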