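# QTL -> nearby bovine genes -> human orthologs -> hypergeometric pathway
# over-representation, per trait and for the combined trait set.

#' Bovine genes within a flank of any QTL member SNP
#'
#' A gene is reported when its span overlaps
#' `[snp_pos - flank_bp, snp_pos + flank_bp]` (1-based inclusive) for any
#' member SNP of any QTL; the flank is measured from SNP positions, not the
#' QTL span ends. Duplicates are collapsed.
#'
#' @param qtl `qtl_calls` with `member_pos` lists
#' @param genes gene_set
#' @param flank_bp flank in bp (default 500,000)
#' @return character vector of bovine gene ids
#' @export
genes_near_qtl <- function(qtl, genes, flank_bp = 5e5) {
  stopifnot(flank_bp >= 0)
  if (!nrow(qtl) || !nrow(genes)) return(character())
  snp_pos <- rbindlist(lapply(seq_len(nrow(qtl)), function(i)
    data.table(chrom = qtl$chrom[i], pos = qtl$member_pos[[i]])))
  .genes_near_positions(snp_pos, genes, flank_bp)
}

.genes_near_positions <- function(snp_pos, genes, flank_bp) {
  hits <- character()
  for (cc in unique(snp_pos$chrom)) {
    pv <- snp_pos[chrom == cc, pos]
    gg <- genes[chrom == cc]
    if (!nrow(gg) || !length(pv)) next
    keep <- vapply(seq_len(nrow(gg)), function(i)
      any(pv >= gg$start[i] - flank_bp & pv <= gg$end[i] + flank_bp),
      logical(1))
    hits <- c(hits, gg$gene_id[keep])
  }
  unique(hits)
}

#' Map bovine gene ids to their human orthologs
#'
#' Returns the union of ortholog sets; bovine genes with no ortholog are
#' dropped and counted in the `n_unmapped` attribute.
#'
#' @param bovine_ids character vector
#' @param om ortholog_map
#' @return character vector of human ids, attribute `n_unmapped`
#' @export
map_orthologs <- function(bovine_ids, om) {
  mapped <- om[bovine %in% bovine_ids]
  human <- unique(mapped$human)
  structure(human, n_unmapped = length(setdiff(bovine_ids, mapped$bovine)))
}

#' Build a gene hit set (hits + background) for one trait
#'
#' Hits are the human orthologs of bovine genes within `flank_bp` of any
#' QTL member SNP; the background is the orthologs of bovine genes within
#' `flank_bp` of any analyzed SNP (the whole post-QC map).
#'
#' @param qtl `qtl_calls` for the trait
#' @param genes gene_set
#' @param om ortholog_map
#' @param map post-QC SNP map (chrom, pos) defining the background
#' @param flank_bp flank in bp
#' @param trait trait label
#' @return list of class `gene_hit_set`: `trait`, `bovine_hits`, `hits`,
#'   `background`, `n_unmapped`
#' @export
build_gene_hit_set <- function(qtl, genes, om, map, flank_bp = 5e5,
                               trait = "trait1") {
  bov_hits <- genes_near_qtl(qtl, genes, flank_bp)
  hits <- map_orthologs(bov_hits, om)
  bg_bov <- .genes_near_positions(as.data.table(map)[, .(chrom, pos)],
                                  genes, flank_bp)
  background <- sort(map_orthologs(bg_bov, om))
  hits <- intersect(hits, background)
  structure(list(trait = trait, bovine_hits = bov_hits,
                 hits = sort(hits), background = background,
                 n_unmapped = attr(map_orthologs(bov_hits, om), "n_unmapped")),
            class = "gene_hit_set")
}

#' Union of per-trait hit sets over a shared background
#' @param per_trait_hits list of `gene_hit_set`
#' @return `gene_hit_set` labelled `"combined"`
#' @export
combined_trait_set <- function(per_trait_hits) {
  stopifnot(length(per_trait_hits) >= 1L)
  bg <- per_trait_hits[[1L]]$background
  for (h in per_trait_hits)
    if (!identical(h$background, bg)) stop("inconsistent backgrounds across traits")
  structure(list(trait = "combined",
                 bovine_hits = unique(unlist(lapply(per_trait_hits, `[[`, "bovine_hits"))),
                 hits = sort(unique(unlist(lapply(per_trait_hits, `[[`, "hits")))),
                 background = bg,
                 n_unmapped = NA_integer_),
            class = "gene_hit_set")
}

#' Hypergeometric pathway over-representation test
#'
#' For each pathway, membership is restricted to the background and the
#' upper-tail probability \eqn{P(X \ge k)} of the hypergeometric
#' distribution with population `N = |background|`, successes
#' `K = |pathway in background|` and draws `n = |hits|` is computed.
#' Raw p-values are reported (no multiplicity correction) with a
#' significance flag at `p < alpha`; set `adjust = "BH"` to add a
#' Benjamini-Hochberg column.
#'
#' @param hits `gene_hit_set`
#' @param pathways pathway_db
#' @param alpha significance threshold on raw p (default 0.05)
#' @param adjust `"none"` (default) or `"BH"`
#' @return data.table of class `pathway_result`: pathway, name, overlap,
#'   n_hits, pathway_size, background_size, p, significant, overlap_genes,
#'   sorted by p
#' @export
enrichment_test <- function(hits, pathways, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  bg <- hits$background
  if (!length(bg)) stop("empty background")
  hh <- intersect(hits$hits, bg)
  N <- length(bg); nh <- length(hh)
  res <- rbindlist(lapply(names(pathways$sets), function(id) {
    pw <- intersect(pathways$sets[[id]], bg)
    K <- length(pw)
    ov <- intersect(pw, hh)
    k <- length(ov)
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, nh, lower.tail = FALSE)
    data.table(pathway = id, name = unname(pathways$descs[id]), overlap = k,
               n_hits = nh, pathway_size = K, background_size = N,
               p = p, overlap_genes = list(sort(ov)))
  }), use.names = TRUE)
  res[, significant := p < alpha]
  if (adjust == "BH") res[, p_bh := p.adjust(p, "BH")]
  setorder(res, p, pathway)
  setattr(res, "class", c("pathway_result", class(data.table())))
  res[]
}

#' Write a pathway over-representation table
#' @param res `pathway_result`
#' @param path file path
#' @param trait trait label written in the first column
#' @export
write_pathways <- function(res, path, trait = "trait1") {
  out <- data.table(trait = trait, res[, .(pathway, name, overlap, pathway_size,
                                           n_hits, background_size, p, significant)],
                    candidate_genes = vapply(res$overlap_genes, paste,
                                             character(1), collapse = ","))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
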