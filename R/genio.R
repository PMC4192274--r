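#' @useDynLib pedgwas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats rnorm rbinom runif rchisq var sd optimize pnorm phyper
#'   smooth.spline predict setNames p.adjust
#' @importFrom utils head tail packageVersion write.table
NULL

.pedgwas_header <- function(seed = NA) {
  sprintf("# pedgwas %s seed=%s", as.character(packageVersion("pedgwas")),
          ifelse(is.na(seed), "NA", as.character(seed)))
}

# ---- GenotypeSet ------------------------------------------------------------

#' Construct a genotype set
#'
#' A `genotype_set` holds a biallelic call matrix (allele counts 0/1/2, `NA`
#' for missing) for `animals x SNPs`, together with a SNP map giving the
#' chromosome label and 1-based bp position of every marker. Columns are
#' stored sorted by (chromosome, position); the call for each SNP is the
#' count of the lexicographically smaller allele.
#'
#' @param calls integer/numeric matrix, animals in rows, SNPs in columns,
#'   entries in `{0,1,2,NA}`.
#' @param map data.frame with columns `chrom`, `snp_id`, `pos` (1-based bp),
#'   one row per column of `calls`, in column order.
#' @param animal_ids character vector of animal identifiers (defaults to
#'   `rownames(calls)`).
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(calls, map, animal_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  map <- as.data.table(map)
  if (!all(c("chrom", "snp_id", "pos") %in% names(map)))
    stop("map must have columns chrom, snp_id, pos")
  if (is.null(animal_ids)) stop("animal_ids required (or rownames on calls)")
  animal_ids <- as.character(animal_ids)
  if (nrow(calls) != length(animal_ids))
    stop("calls has ", nrow(calls), " rows but ", length(animal_ids), " animal ids")
  if (ncol(calls) != nrow(map))
    stop("calls has ", ncol(calls), " columns but map has ", nrow(map), " rows")
  if (anyDuplicated(map$snp_id))
    stop("duplicated snp_ids: ", paste(head(unique(map$snp_id[duplicated(map$snp_id)]), 3), collapse = ", "))
  if (anyDuplicated(animal_ids)) stop("duplicated animal ids")
  bad <- !(calls %in% c(0, 1, 2) | is.na(calls))
  if (any(bad)) stop("calls must be 0/1/2/NA")
  ord <- order(map$chrom, map$pos)
  map <- map[ord]
  calls <- calls[, ord, drop = FALSE]
  dup <- map[, .N, by = .(chrom, pos)][N > 1L]
  if (nrow(dup))
    stop("positions do not strictly increase within chromosome ", dup$chrom[1L])
  dimnames(calls) <- list(animal_ids, map$snp_id)
  structure(list(animal_ids = animal_ids, snp_ids = map$snp_id,
                 calls = calls, map = map),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d animals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              length(x$animal_ids), length(x$snp_ids),
              length(unique(x$map$chrom)), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Subset a genotype set by SNP and/or animal
#' @param gs genotype_set
#' @param snp_ids SNPs to keep (default all)
#' @param animal_ids animals to keep (default all)
#' @return genotype_set restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(gs, snp_ids = gs$snp_ids, animal_ids = gs$animal_ids) {
  stopifnot(inherits(gs, "genotype_set"))
  if (!all(snp_ids %in% gs$snp_ids)) stop("unknown snp id(s)")
  if (!all(animal_ids %in% gs$animal_ids)) stop("unknown animal id(s)")
  keep <- gs$map$snp_id %in% snp_ids
  genotype_set(gs$calls[match(animal_ids, gs$animal_ids), keep, drop = FALSE],
               gs$map[keep], animal_ids)
}

# ---- Pedigree ---------------------------------------------------------------

#' Construct a pedigree
#'
#' Records of (animal, sire, dam) with `NA` for unknown parents. The parent
#' graph must be acyclic; rows are stored in a topological order (parents
#' before offspring).
#'
#' @param df data.frame with columns `animal`, `sire`, `dam` (character;
#'   `NA` or `"0"` = unknown).
#' @return data.table of class `pedigree` in topological order.
#' @export
pedigree <- function(df) {
  ped <- as.data.table(df)[, .(animal = as.character(animal),
                               sire = as.character(sire),
                               dam = as.character(dam))]
  ped[sire %in% c("0", ""), sire := NA_character_]
  ped[dam %in% c("0", ""), dam := NA_character_]
  if (anyDuplicated(ped$animal)) stop("duplicated animal in pedigree")
  miss <- setdiff(c(ped$sire, ped$dam), c(ped$animal, NA))
  if (length(miss)) {
    # parents that appear only as parents become founders
    ped <- rbind(data.table(animal = miss, sire = NA_character_, dam = NA_character_), ped)
  }
  ord <- .topo_order(ped)
  if (is.null(ord)) stop("pedigree contains a cycle (an animal is its own ancestor)")
  ped <- ped[ord]
  setattr(ped, "class", c("pedigree", class(data.table())))
  ped[]
}

# Kahn topological sort; NULL if cyclic.
.topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  indeg <- integer(n)
  kids <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(si[k], di[k])) if (!is.na(p)) {
      indeg[k] <- indeg[k] + 1L
      kids[[p]] <- c(kids[[p]], k)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != n) return(NULL)
  out
}

# ---- PhenotypeTable ---------------------------------------------------------

#' Construct a phenotype table
#'
#' One record per animal-trait pair: the de-regressed PTA (`drp`), its
#' reliability in `[0,1]`, and (simulation only) the true genetic value.
#'
#' @param df data.frame with columns `animal`, `trait`, `drp`, `reliability`
#'   and optionally `true_g`.
#' @return data.table of class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  ph <- as.data.table(df)
  req <- c("animal", "trait", "drp", "reliability")
  if (!all(req %in% names(ph))) stop("phenotypes need columns ", paste(req, collapse = ", "))
  ph[, animal := as.character(animal)][, trait := as.character(trait)]
  if (any(ph$reliability < 0 | ph$reliability > 1, na.rm = TRUE))
    stop("reliability outside [0,1]")
  if (anyDuplicated(ph[, .(animal, trait)]))
    stop("more than one record for an animal-trait pair")
  setattr(ph, "class", c("phenotype_table", class(data.table())))
  ph[]
}

# ---- GeneSet / OrthologMap / PathwayDB -------------------------------------

#' Construct a gene set (genomic intervals, 1-based inclusive)
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @return data.table of class `gene_set`.
#' @export
gene_set <- function(df) {
  gs <- as.data.table(df)[, .(gene_id = as.character(gene_id),
                              chrom = as.character(chrom),
                              start = as.integer(start), end = as.integer(end))]
  if (any(gs$start > gs$end)) stop("gene start > end")
  if (anyDuplicated(gs$gene_id)) stop("duplicated gene_id")
  setattr(gs, "class", c("gene_set", class(data.table())))
  gs[]
}

#' Construct a bovine-to-human ortholog map
#' @param df data.frame with columns `bovine`, `human`; a bovine gene may map
#'   to several human genes (one row each) or to none (absent).
#' @return data.table of class `ortholog_map`.
#' @export
ortholog_map <- function(df) {
  om <- unique(as.data.table(df)[, .(bovine = as.character(bovine),
                                     human = as.character(human))])
  setattr(om, "class", c("ortholog_map", class(data.table())))
  om[]
}

#' Construct a pathway database
#' @param pathways named list; each element a character vector of human gene
#'   ids, names are pathway ids. Optionally give descriptions via `descs`.
#' @param descs named character vector of descriptions (default = ids).
#' @return object of class `pathway_db`.
#' @export
pathway_db <- function(pathways, descs = NULL) {
  if (is.null(names(pathways)) || any(names(pathways) == ""))
    stop("pathways must be a named list")
  if (any(lengths(pathways) == 0L)) stop("empty pathway gene set")
  pathways <- lapply(pathways, function(g) unique(as.character(g)))
  if (is.null(descs)) descs <- setNames(names(pathways), names(pathways))
  structure(list(sets = pathways, descs = descs), class = "pathway_db")
}

# ---- Readers / writers ------------------------------------------------------

#' Write a genotype set as a PED/MAP pair
#'
#' PED rows are `fam id sire dam sex pheno` followed by two allele letters per
#' SNP (`A`/`B`; missing = `0 0`); the MAP has columns chrom, snp id, 0, bp.
#'
#' @param gs genotype_set
#' @param ped_path,map_path output paths
#' @param seed seed recorded in the header comment
#' @export
write_genotypes <- function(gs, ped_path, map_path, seed = NA) {
  stopifnot(inherits(gs, "genotype_set"))
  hdr <- .pedgwas_header(seed)
  writeLines(c(hdr, gs$map[, paste(chrom, snp_id, 0L, pos)]), map_path)
  n <- nrow(gs$calls)
  allele <- matrix("0", n, 2L * ncol(gs$calls))
  for (j in seq_len(ncol(gs$calls))) {
    g <- gs$calls[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, "A", "B"))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, "A", "B"))
    allele[, 2L * j - 1L] <- a1
    allele[, 2L * j] <- a2
  }
  lead <- cbind("FAM", gs$animal_ids, "0", "0", "0", "-9")
  lines <- apply(cbind(lead, allele), 1L, paste, collapse = " ")
  writeLines(c(hdr, lines), ped_path)
  invisible(NULL)
}

#' Read a PED/MAP genotype pair
#'
#' Allele pairs collapse to counts of the lexicographically smaller allele
#' observed at each SNP; `0 0` becomes missing. Sites with more than two
#' distinct alleles, ragged rows, or duplicated ids are rejected.
#'
#' @param ped_path,map_path input paths
#' @return genotype_set
#' @export
read_genotypes <- function(ped_path, map_path) {
  map_lines <- grep("^#", readLines(map_path), invert = TRUE, value = TRUE)
  mp <- fread(text = map_lines, header = FALSE,
              col.names = c("chrom", "snp_id", "cm", "pos"),
              colClasses = list(character = 1:2))
  ped_lines <- grep("^#", readLines(ped_path), invert = TRUE, value = TRUE)
  toks <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * nrow(mp)
  lens <- lengths(toks)
  if (any(lens != want))
    stop("ragged PED row (line ", which(lens != want)[1L], "): expected ",
         want, " fields, found ", lens[lens != want][1L])
  tok <- do.call(rbind, toks)
  animal_ids <- tok[, 2L]
  if (anyDuplicated(animal_ids)) stop("duplicate animal id in PED")
  n <- length(animal_ids); m <- nrow(mp)
  calls <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    a1 <- tok[, 6L + 2L * j - 1L]; a2 <- tok[, 6L + 2L * j]
    obs <- c(a1, a2)
    als <- sort(unique(obs[obs != "0"]))
    if (length(als) > 2L)
      stop("SNP ", mp$snp_id[j], " has >2 alleles: ", paste(als, collapse = ","))
    if (length(als) == 0L) next  # all missing
    ref <- als[1L]  # lexicographically smaller allele is counted
    miss <- a1 == "0" | a2 == "0"
    calls[, j] <- (a1 == ref) + (a2 == ref)
    calls[miss, j] <- NA_real_
  }
  genotype_set(calls, mp[, .(chrom, snp_id, pos)], animal_ids)
}

#' Write / read a pedigree CSV (animal,sire,dam; 0 = unknown)
#' @param ped pedigree
#' @param path file path
#' @param seed seed recorded in the header
#' @export
write_pedigree <- function(ped, path, seed = NA) {
  out <- as.data.table(ped)[, .(animal,
                                sire = fifelse(is.na(sire), "0", sire),
                                dam = fifelse(is.na(dam), "0", dam))]
  writeLines(c(.pedgwas_header(seed), "animal,sire,dam",
               out[, paste(animal, sire, dam, sep = ",")]), path)
  invisible(NULL)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  pedigree(fread(text = lines, header = TRUE, colClasses = "character"))
}

#' Write / read a phenotype TSV (animal, trait, drp, reliability[, true_g])
#' @param ph phenotype_table
#' @param path file path
#' @param seed seed recorded in the header
#' @export
write_phenotypes <- function(ph, path, seed = NA) {
  con <- file(path, "w")
  writeLines(.pedgwas_header(seed), con)
  write.table(as.data.frame(ph), con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(NULL)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  phenotype_table(fread(text = lines, header = TRUE))
}

#' Write / read genes as BED (0-based half-open on disk, 1-based inclusive
#' internally)
#' @param genes gene_set
#' @param path file path
#' @param seed seed recorded in the header
#' @export
write_genes_bed <- function(genes, path, seed = NA) {
  writeLines(c(.pedgwas_header(seed),
               genes[, paste(chrom, start - 1L, end, gene_id, sep = "\t")]), path)
  invisible(NULL)
}

#' @rdname write_genes_bed
#' @export
read_genes_bed <- function(path) {
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  bed <- fread(text = lines, header = FALSE,
               col.names = c("chrom", "start0", "end0", "gene_id"),
               colClasses = list(character = c(1L, 4L)))
  gene_set(bed[, .(gene_id, chrom, start = start0 + 1L, end = end0)])
}

#' Write / read a two-column bovine-to-human ortholog TSV
#' @param om ortholog_map
#' @param path file path
#' @param seed seed recorded in the header
#' @export
write_orthologs <- function(om, path, seed = NA) {
  writeLines(c(.pedgwas_header(seed), "bovine\thuman",
               om[, paste(bovine, human, sep = "\t")]), path)
  invisible(NULL)
}

#' @rdname write_orthologs
#' @export
read_orthologs <- function(path) {
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  ortholog_map(fread(text = lines, header = TRUE, colClasses = "character"))
}

#' Write / read pathway gene sets in GMT format
#' @param db pathway_db
#' @param path file path
#' @param seed seed recorded in the header
#' @export
write_gmt <- function(db, path, seed = NA) {
  lines <- vapply(names(db$sets), function(id)
    paste(c(id, db$descs[[id]], db$sets[[id]]), collapse = "\t"), character(1))
  writeLines(c(.pedgwas_header(seed), lines), path)
  invisible(NULL)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(toks) < 3L)
  if (length(short)) stop("GMT line ", short[1L], " has no genes")
  ids <- vapply(toks, `[`, character(1), 1L)
  descs <- setNames(vapply(toks, `[`, character(1), 2L), ids)
  sets <- setNames(lapply(toks, function(t) t[-(1:2)]), ids)
  pathway_db(sets, descs)
}
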