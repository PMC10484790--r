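# Synthetic fixture bundles: proteins with planted low-tolerance domains,
# labeled variant benchmarks with controlled bimodal score distributions,
# exon-skipping isoform groups, and DMS-like tables with a known monotone
# relation between planted effects and measurements. Everything is
# generated from a seed and is byte-reproducible.

#' Specification for a synthetic fixture bundle
#'
#' Defaults describe a desk-scale but realistically structured world:
#' proteins of 150-400 residues, one planted functional domain each with a
#' very low mutation tolerance (0.001, giving substitution LLRs around
#' -10, the scale seen for pathogenic variants), benign and pathogenic
#' benchmark score distributions N(-3, 1.5^2) and N(-12, 2^2), and
#' exon-skipping isoform groups in which the excised segment truncates the
#' domain (so the domain's constraint disappears from the short isoform).
#'
#' @param n_proteins Number of benchmark proteins.
#' @param length_range Protein length range (uniform).
#' @param domain_width Width of each planted domain.
#' @param domain_tolerance Non-wild-type probability mass inside domains.
#' @param n_benign,n_pathogenic Benchmark variants per class.
#' @param benign_mean,benign_sd,pathogenic_mean,pathogenic_sd Class score
#'   distributions.
#' @param n_isoform_groups Exon-skipping gene groups.
#' @param n_domain_variants,n_distal_variants Cross-isoform variants per
#'   group near to / far from the skipped segment.
#' @param n_dms_genes,n_dms_variants DMS table dimensions.
#' @param seed Master seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 6L, length_range = c(150L, 400L),
                         domain_width = 40L, domain_tolerance = 0.001,
                         n_benign = 300L, n_pathogenic = 300L,
                         benign_mean = -3, benign_sd = 1.5,
                         pathogenic_mean = -12, pathogenic_sd = 2,
                         n_isoform_groups = 3L, n_domain_variants = 6L,
                         n_distal_variants = 6L, n_dms_genes = 3L,
                         n_dms_variants = 30L, seed = 1L) {
  spec <- as.list(environment())
  stopifnot(n_proteins >= 1, length_range[1] >= 60,
            domain_width < length_range[1] / 2,
            n_benign >= 2, n_pathogenic >= 2)
  class(spec) <- "fixture_spec"
  spec
}

random_protein <- function(id, L) {
  protein_sequence(id, paste(sample(.AA, L, replace = TRUE), collapse = ""))
}

#' Generate a synthetic fixture bundle
#'
#' @param spec A [fixture_spec()].
#' @return List of class `fixture_bundle` with elements `proteins` (named
#'   list), `domains` (`data.frame`), `backend` (synthetic backend with the
#'   domains planted), `benchmark` (variant table with `label`, `score`,
#'   `score_alt` and gene ids), `isoform_groups` (per-gene isoform lists,
#'   variant maps and splice-junction tables), `dms` (assay table with
#'   `measurement`, `prediction`, `x_wt`, `center_transform`), and
#'   `manifest` (all generating parameters).
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    # --- proteins with one planted domain each ---------------------------
    lens <- sample(spec$length_range[1]:spec$length_range[2],
                   spec$n_proteins, replace = TRUE)
    proteins <- list()
    domains <- data.frame()
    for (i in seq_len(spec$n_proteins)) {
      id <- sprintf("PROT%02d", i)
      proteins[[id]] <- random_protein(id, lens[i])
      dstart <- sample(20:(lens[i] - spec$domain_width - 19L), 1L)
      domains <- rbind(domains, data.frame(
        seq_id = id, start = dstart, end = dstart + spec$domain_width - 1L,
        tolerance = spec$domain_tolerance))
    }

    # --- labeled benchmark with bimodal scores ---------------------------
    n <- spec$n_benign + spec$n_pathogenic
    label <- c(rep(FALSE, spec$n_benign), rep(TRUE, spec$n_pathogenic))
    score <- c(stats::rnorm(spec$n_benign, spec$benign_mean, spec$benign_sd),
               stats::rnorm(spec$n_pathogenic, spec$pathogenic_mean,
                            spec$pathogenic_sd))
    gene <- sample(names(proteins), n, replace = TRUE)
    hgvs <- character(n)
    for (i in seq_len(n)) {
      p <- proteins[[gene[i]]]
      pos <- sample.int(p$length, 1L)
      ref <- substr(p$residues, pos, pos)
      alt <- sample(setdiff(.AA, ref), 1L)
      hgvs[i] <- sprintf("p.%s%d%s", .AA3[ref], pos, .AA3[alt])
    }
    benchmark <- data.frame(
      variant_id = sprintf("var%04d", seq_len(n)),
      gene_id = gene, hgvs = hgvs,
      label = ifelse(label, "pathogenic", "benign"),
      score = score,
      score_alt = score + stats::rnorm(n, 0, 4)  # a weaker comparator method
    )

    # --- exon-skipping isoform groups ------------------------------------
    isoform_groups <- list()
    for (g in seq_len(spec$n_isoform_groups)) {
      gid <- sprintf("ISOG%02d", g)
      L <- 300L
      full <- random_protein(paste0(gid, ".1"), L)
      dstart <- 101L
      dend <- dstart + spec$domain_width - 1L
      skip_start <- dstart + spec$domain_width %/% 2L  # removes the domain tail
      skip_end <- skip_start + 59L
      short <- protein_sequence(
        paste0(gid, ".2"),
        paste0(substr(full$residues, 1L, skip_start - 1L),
               substr(full$residues, skip_end + 1L, L)))
      # the skipped segment truncates the domain, destroying its constraint
      # in the short isoform: only the full isoform carries the domain
      domains <- rbind(domains, data.frame(
        seq_id = full$id, start = dstart, end = dend,
        tolerance = spec$domain_tolerance))
      near_pos <- sample(dstart:(skip_start - 1L), spec$n_domain_variants)
      far_pos <- sample(5:60, spec$n_distal_variants)
      map <- data.frame()
      for (pos in c(near_pos, far_pos)) {
        ref <- substr(full$residues, pos, pos)
        alt <- sample(setdiff(.AA, ref), 1L)
        vid <- sprintf("%s_p%d%s", gid, pos, alt)
        # positions before skip_start keep their coordinate in both isoforms
        map <- rbind(map,
          data.frame(variant_id = vid, isoform_id = full$id, position = pos,
                     ref = ref, alt = alt, absent = FALSE),
          data.frame(variant_id = vid, isoform_id = short$id, position = pos,
                     ref = ref, alt = alt, absent = FALSE))
      }
      junctions <- data.frame(
        isoform_id = c(full$id, full$id, short$id),
        junction_aa = c(skip_start - 1L, skip_end, skip_start - 1L))
      isoform_groups[[gid]] <- list(
        gene_id = gid,
        isoforms = stats::setNames(list(full, short), c(full$id, short$id)),
        primary_isoform_id = full$id,
        variant_map = map, junctions = junctions,
        skip_segment = c(skip_start, skip_end),
        near_variant_ids = unique(map$variant_id[map$position %in% near_pos]),
        far_variant_ids = unique(map$variant_id[map$position %in% far_pos]))
    }

    # --- DMS tables with a known monotone effect-measurement relation ----
    dms <- data.frame()
    for (g in seq_len(spec$n_dms_genes)) {
      gid <- sprintf("DMSG%02d", g)
      for (a in seq_len(1L + (g %% 2L))) {
        eff <- c(stats::rnorm(spec$n_dms_variants %/% 2, -2, 1.2),
                 stats::rnorm(spec$n_dms_variants -
                                spec$n_dms_variants %/% 2, -10, 2))
        meas <- stats::plogis(eff / 2 + 4) +
          stats::rnorm(length(eff), 0, 0.05)
        dms <- rbind(dms, data.frame(
          gene_id = gid, assay_id = sprintf("%s_assay%d", gid, a),
          variant = sprintf("%s_a%d_v%02d", gid, a, seq_along(eff)),
          measurement = meas, prediction = eff,
          x_wt = 1, center_transform = FALSE))
      }
    }

    backend <- synthetic_backend(seed = spec$seed, domain_spec = domains)
    structure(list(proteins = proteins, domains = domains, backend = backend,
                   benchmark = benchmark, isoform_groups = isoform_groups,
                   dms = dms,
                   manifest = unclass(spec)),
              class = "fixture_bundle")
  })
}

#' Write a fixture bundle to plain-text files
#'
#' Emits `proteins.fasta`, `domains.tsv`, `benchmark.tsv`, `dms.tsv`,
#' per-group isoform FASTA/map/junction files and `manifest.json` under
#' `dir`.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$proteins, file.path(dir, "proteins.fasta"))
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(bundle$domains, "domains.tsv")
  write_tsv(bundle$benchmark, "benchmark.tsv")
  write_tsv(bundle$dms, "dms.tsv")
  for (gid in names(bundle$isoform_groups)) {
    grp <- bundle$isoform_groups[[gid]]
    write_fasta(grp$isoforms, file.path(dir, paste0(gid, ".fasta")))
    write_tsv(grp$variant_map, paste0(gid, "_map.tsv"))
    write_tsv(grp$junctions, paste0(gid, "_junctions.tsv"))
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
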