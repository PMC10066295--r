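## Synteny-anchored loss calling. Anchor-species genes from contracting
## orthologous groups are located in each target species via the orthologs
## of their syntenic neighborhood; the bounded target interval is then
## scanned with the translated search for remnants of the anchor gene.
## Calls: retained (ortholog annotated), decayed (remnant hit, E < 1e-5),
## deleted (interval found, no remnant), non_informative (no interval).

#' Bundle a genome's annotation and sequence
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based closed coordinates, GFF3 convention).
#' @param seq A [Biostrings::DNAStringSet] named by chromosome/scaffold.
#' @return Object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, seq) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("genes must have columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (any(genes$start > genes$end)) stop("start must be <= end")
  bad <- !(genes$chrom %in% names(seq))
  if (any(bad)) {
    stop("genes on unknown scaffolds: ",
         paste(utils::head(genes$gene_id[bad]), collapse = ", "))
  }
  over <- genes$end > Biostrings::width(seq)[match(genes$chrom, names(seq))]
  if (any(over)) stop("gene coordinates exceed scaffold bounds")
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, seq = seq), class = "genome_annotation")
}

#' Read a genome from FASTA + GFF3 files
#'
#' Sequences are read with \pkg{Biostrings}, features with
#' \pkg{rtracklayer}; features of type `gene` (or all features if no `gene`
#' type is present) become the gene table.
#'
#' @param fasta Path to a FASTA file.
#' @param gff3 Path to a GFF3 file whose features carry `ID` attributes.
#' @return A [genome_annotation()].
#' @export
read_genome <- function(fasta, gff3) {
  seq <- Biostrings::readDNAStringSet(fasta)
  names(seq) <- sub("\\s.*$", "", names(seq))
  gr <- rtracklayer::import(gff3)
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) {
    gr <- gr[gr$type == "gene"]
  }
  genes <- data.frame(
    gene_id = gr$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  genome_annotation(genes, seq)
}

#' Extract a gene's (strand-aware) sequence
#'
#' @param annot A [genome_annotation()].
#' @param gene_id Gene identifier.
#' @return Character DNA sequence, reverse-complemented for `-` genes.
#' @export
gene_sequence <- function(annot, gene_id) {
  g <- annot$genes[annot$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene id: ", gene_id)
  s <- Biostrings::subseq(annot$seq[[g$chrom]], g$start, g$end)
  if (g$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Read an ortholog membership table
#'
#' @param path TSV with columns `group_id`, `species`, `gene_id`.
#' @return Data frame (long format) of class `ortholog_table`.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  as_ortholog_table(tab)
}

#' @rdname read_ortholog_table
#' @param tab Data frame with columns `group_id`, `species`, `gene_id`.
#' @export
as_ortholog_table <- function(tab) {
  req <- c("group_id", "species", "gene_id")
  if (!all(req %in% names(tab))) {
    stop("ortholog table needs columns ", paste(req, collapse = ", "))
  }
  class(tab) <- c("ortholog_table", "data.frame")
  tab
}

orthologs_of <- function(table, gene_id, from_species, to_species) {
  grp <- unique(table$group_id[table$species == from_species &
                               table$gene_id == gene_id])
  if (length(grp) == 0) return(character())
  unique(table$gene_id[table$group_id %in% grp &
                       table$species == to_species])
}

#' Select anchor loci from contracting groups
#'
#' All anchor-species genes belonging to contracting groups whose scaffold
#' is among the assembled chromosomes; genes on unplaced scaffolds are
#' reported as filtered.
#'
#' @param table An ortholog table (see [as_ortholog_table()]).
#' @param anchor_annot The anchor species' [genome_annotation()].
#' @param contracting_ids Group ids to analyse (must exist in `table`).
#' @param chromosome_ids Scaffold names counted as assembled chromosomes.
#' @param anchor_species Anchor species name as used in `table`.
#' @return List with `selected` (gene ids) and `filtered` (data frame
#'   `gene_id`, `reason`).
#' @export
select_anchor_loci <- function(table, anchor_annot, contracting_ids,
                               chromosome_ids, anchor_species) {
  unknown <- setdiff(contracting_ids, unique(table$group_id))
  if (length(unknown) > 0) {
    stop("unknown group ids: ", paste(unknown, collapse = ", "))
  }
  genes <- unique(table$gene_id[table$group_id %in% contracting_ids &
                                table$species == anchor_species])
  if (length(genes) == 0) {
    return(list(selected = character(),
                filtered = data.frame(gene_id = character(),
                                      reason = character())))
  }
  chrom <- anchor_annot$genes$chrom[match(genes, anchor_annot$genes$gene_id)]
  missing <- is.na(chrom)
  placed <- !missing & chrom %in% chromosome_ids
  filtered <- data.frame(
    gene_id = genes[!placed],
    reason = ifelse(missing[!placed], "not_in_annotation",
                    "unplaced_scaffold"))
  list(selected = genes[placed], filtered = filtered)
}

#' Build the syntenic neighborhood of an anchor gene
#'
#' Up to `window` flanking genes on each side of the anchor, in
#' chromosomal order moving away from the anchor; truncated at chromosome
#' ends.
#'
#' @param anchor_gene Anchor gene id.
#' @param annot The anchor species' [genome_annotation()].
#' @param window Genes per side (>= 1, default 5).
#' @return List of class `syntenic_neighborhood` with `anchor_gene`,
#'   `upstream`, `downstream`, `window`.
#' @export
build_neighborhood <- function(anchor_gene, annot, window = 5L) {
  if (window < 1) stop("window must be >= 1")
  g <- annot$genes
  row <- which(g$gene_id == anchor_gene)
  if (length(row) != 1) stop("anchor gene not in annotation: ", anchor_gene)
  chr_genes <- g[g$chrom == g$chrom[row], , drop = FALSE]
  pos <- which(chr_genes$gene_id == anchor_gene)
  up_idx <- rev(seq_len(pos - 1L))            # nearest first
  up_idx <- up_idx[seq_len(min(window, length(up_idx)))]
  dn_idx <- seq(pos + 1L, length.out = min(window, nrow(chr_genes) - pos))
  structure(list(anchor_gene = anchor_gene,
                 upstream = chr_genes$gene_id[up_idx],
                 downstream = chr_genes$gene_id[dn_idx],
                 window = as.integer(window)),
            class = "syntenic_neighborhood")
}

#' Map a syntenic neighborhood onto a target species
#'
#' Looks up target-species orthologs of the neighborhood genes. If at
#' least one upstream and one downstream ortholog land on a single target
#' scaffold with the two innermost flanks non-overlapping, returns the
#' interval spanning those innermost flanking orthologs (intergenic
#' sequence included); otherwise `NULL` (synteny lost, the locus is
#' non-informative downstream). When several scaffolds qualify, the one
#' with the most mapped neighborhood orthologs is used. Strand is ignored
#' (inversions within a block are tolerated).
#'
#' @param nbhd A [build_neighborhood()] result.
#' @param table Ortholog table.
#' @param target_annot Target species' [genome_annotation()].
#' @param anchor_species,target_species Species names as used in `table`.
#' @return List with `scaffold`, `start`, `end`, `left_gene`, `right_gene`,
#'   or `NULL`.
#' @export
map_neighborhood <- function(nbhd, table, target_annot,
                             anchor_species, target_species) {
  map_side <- function(ids) {
    # returns data frame of target genes for each neighborhood gene,
    # nearest anchor-neighbors first
    out <- list()
    for (i in seq_along(ids)) {
      tg <- orthologs_of(table, ids[i], anchor_species, target_species)
      tg <- tg[tg %in% target_annot$genes$gene_id]
      if (length(tg) > 0) {
        out[[length(out) + 1L]] <- data.frame(rank = i, gene_id = tg)
      }
    }
    if (length(out) == 0) return(NULL)
    do.call(rbind, out)
  }
  up <- map_side(nbhd$upstream)
  dn <- map_side(nbhd$downstream)
  if (is.null(up) || is.null(dn)) return(NULL)
  g <- target_annot$genes
  up$chrom <- g$chrom[match(up$gene_id, g$gene_id)]
  dn$chrom <- g$chrom[match(dn$gene_id, g$gene_id)]
  shared <- intersect(unique(up$chrom), unique(dn$chrom))
  if (length(shared) == 0) return(NULL)
  n_mapped <- vapply(shared, function(ch) {
    sum(up$chrom == ch) + sum(dn$chrom == ch)
  }, numeric(1))
  for (ch in shared[order(-n_mapped, shared)]) {
    u <- up[up$chrom == ch, ]; u <- u[order(u$rank), ][1, ]
    d <- dn[dn$chrom == ch, ]; d <- d[order(d$rank), ][1, ]
    ug <- g[g$gene_id == u$gene_id, ]
    dg <- g[g$gene_id == d$gene_id, ]
    lo <- if (ug$start <= dg$start) ug else dg
    hi <- if (ug$start <= dg$start) dg else ug
    if (lo$end >= hi$start) next          # overlapping flanks: incompatible
    return(list(scaffold = ch, start = lo$start, end = hi$end,
                left_gene = lo$gene_id, right_gene = hi$gene_id))
  }
  NULL
}

#' Call a locus retained / decayed / deleted / non-informative
#'
#' The decision rule: an annotated ortholog means retained (no sequence
#' check); no syntenic interval means non-informative; otherwise the anchor
#' gene is searched against the interval with [translated_search()] — a hit
#' with `E < threshold` means decayed (remnant present), none means
#' deleted.
#'
#' @param anchor_dna Anchor gene DNA (character), non-empty.
#' @param subject_dna Target interval DNA, or `NULL` when no interval.
#' @param ortholog_present Is an annotated ortholog present in the target?
#' @param threshold E-value threshold (default `1e-5`).
#' @param scoring A [scoring_scheme()].
#' @return List with `call`, `best_hit` (row of search hits or `NULL`).
#' @export
call_locus <- function(anchor_dna, subject_dna, ortholog_present,
                       threshold = 1e-5, scoring = scoring_scheme()) {
  if (ortholog_present) {
    return(list(call = "retained", best_hit = NULL))
  }
  if (!nzchar(anchor_dna)) stop("anchor sequence is empty")
  if (is.null(subject_dna)) {
    return(list(call = "non_informative", best_hit = NULL))
  }
  if (nchar(subject_dna) < 3) {
    return(list(call = "deleted", best_hit = NULL))
  }
  hits <- translated_search(anchor_dna, subject_dna, scoring, threshold)
  if (nrow(hits) > 0) {
    list(call = "decayed", best_hit = hits[1, ])
  } else {
    list(call = "deleted", best_hit = NULL)
  }
}

#' Classify every anchor locus in every target species
#'
#' Runs the full caller: anchor selection, neighborhood construction,
#' synteny mapping, and per-locus calling, then bins cross-species loss
#' patterns and tests the per-species loss-mechanism counts against a
#' uniform distribution.
#'
#' @param genomes Named list of [genome_annotation()] objects, one per
#'   species (anchor included).
#' @param table Ortholog table covering all species.
#' @param contracting_ids Group ids to analyse.
#' @param anchor_species Name of the anchor species in `genomes`/`table`.
#' @param species_tree [ape::phylo] (or Newick path/string) over the target
#'   species, used for cryptic-pattern detection; `NULL` skips it.
#' @param chromosome_ids Scaffolds counted as chromosomes (default: all
#'   scaffolds of the anchor genome).
#' @param window Syntenic-neighborhood size per side (default 5).
#' @param threshold Remnant-search E-value threshold (default `1e-5`).
#' @param scoring A [scoring_scheme()].
#' @return Object of class `loss_calls`: list with `calls` (data frame:
#'   `anchor_gene`, `species`, `call`, `best_evalue`, `scaffold`, `start`,
#'   `end`), `patterns` (from [classify_patterns()]), `summary` (from
#'   [summarize_events()]), `chisq` (per-species decayed/deleted counts vs
#'   uniform), and `parameters`.
#' @export
classify_loss <- function(genomes, table, contracting_ids, anchor_species,
                          species_tree = NULL,
                          chromosome_ids = NULL, window = 5L,
                          threshold = 1e-5, scoring = scoring_scheme()) {
  if (!anchor_species %in% names(genomes)) {
    stop("anchor species missing from genomes")
  }
  anchor_annot <- genomes[[anchor_species]]
  if (is.null(chromosome_ids)) chromosome_ids <- names(anchor_annot$seq)
  targets <- setdiff(names(genomes), anchor_species)
  sel <- select_anchor_loci(table, anchor_annot, contracting_ids,
                            chromosome_ids, anchor_species)
  rows <- list()
  for (anchor in sel$selected) {
    nbhd <- build_neighborhood(anchor, anchor_annot, window)
    anchor_dna <- gene_sequence(anchor_annot, anchor)
    for (sp in targets) {
      present <- length(orthologs_of(table, anchor, anchor_species, sp)) > 0
      interval <- NULL
      subject <- NULL
      if (!present) {
        interval <- map_neighborhood(nbhd, table, genomes[[sp]],
                                     anchor_species, sp)
        if (!is.null(interval)) {
          subject <- as.character(Biostrings::subseq(
            genomes[[sp]]$seq[[interval$scaffold]],
            interval$start, interval$end))
        }
      }
      res <- call_locus(anchor_dna, subject, present, threshold, scoring)
      rows[[length(rows) + 1L]] <- data.frame(
        anchor_gene = anchor, species = sp, call = res$call,
        best_evalue = if (is.null(res$best_hit)) NA_real_
                      else res$best_hit$evalue,
        scaffold = if (is.null(interval)) NA_character_ else interval$scaffold,
        start = if (is.null(interval)) NA_integer_ else interval$start,
        end = if (is.null(interval)) NA_integer_ else interval$end)
    }
  }
  calls <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(anchor_gene = character(), species = character(),
               call = character(), best_evalue = numeric(),
               scaffold = character(), start = integer(), end = integer())
  patterns <- if (nrow(calls) > 0) classify_patterns(calls, species_tree)
              else NULL
  summary_tabs <- if (nrow(calls) > 0) summarize_events(patterns, calls)
                  else NULL
  chisq <- NULL
  if (nrow(calls) > 0) {
    mech <- table_counts(calls$call[calls$call %in% c("decayed", "deleted")])
    if (length(mech) >= 2 && sum(mech) > 0) {
      chisq <- chisq_uniform(mech)
    }
  }
  structure(list(calls = calls, patterns = patterns, summary = summary_tabs,
                 chisq = chisq, filtered_anchors = sel$filtered,
                 parameters = list(window = window, threshold = threshold,
                                   anchor_species = anchor_species,
                                   chromosome_ids = chromosome_ids)),
            class = "loss_calls")
}

table_counts <- function(x) {
  tb <- table(x)
  stats::setNames(as.integer(tb), names(tb))
}

#' @export
print.loss_calls <- function(x, ...) {
  cat(sprintf("Loss calls: %d anchor loci x %d target species (window = %d, E < %g)\n",
              length(unique(x$calls$anchor_gene)),
              length(unique(x$calls$species)),
              x$parameters$window, x$parameters$threshold))
  if (!is.null(x$summary)) {
    cat("\nPer-species calls:\n")
    print(x$summary$per_species)
    cat("\nCross-species clusters:\n")
    print(x$summary$clusters)
  }
  if (!is.null(x$chisq)) {
    cat(sprintf("\nDecay vs deletion, chi-square GOF vs uniform: X2 = %.3f, df = %d, p = %.3g\n",
                x$chisq$statistic, x$chisq$df, x$chisq$p_value))
  }
  invisible(x)
}

## tip sets of every clade (internal node) of a rooted tree, plus singletons
tree_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  clades <- lapply(seq_len(n_tip), function(i) tree$tip.label[i])
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    tips <- ape::extract.clade(tree, node)$tip.label
    clades[[length(clades) + 1L]] <- tips
  }
  clades
}

#' Bin cross-species loss patterns
#'
#' For each anchor gene, the pattern bin is the subset of target species in
#' which the locus was lost (decayed or deleted). A pattern is cryptic
#' unless the subset is empty or forms exactly one monophyletic clade on
#' the species tree (a single loss event under parsimony). The cluster
#' label follows the loss-mechanism roll-up: `retained_all` with no losses,
#' `decayed_cluster` with at least one decay signature, `deleted_cluster`
#' when every loss is a deletion.
#'
#' @param calls Data frame with columns `anchor_gene`, `species`, `call`
#'   (one row per pair, complete).
#' @param species_tree Rooted [ape::phylo] (or Newick path/string) over the
#'   target species; `NULL` leaves `cryptic` as `NA`.
#' @return Data frame: `anchor_gene`, `bin` (comma-joined lost species, or
#'   `"none"`), `n_lost`, `cryptic`, `cluster`.
#' @export
classify_patterns <- function(calls, species_tree = NULL) {
  species <- sort(unique(calls$species))
  anchors <- unique(calls$anchor_gene)
  counts <- table(calls$anchor_gene)
  if (any(counts != length(species))) {
    stop("every anchor gene needs a call for every target species")
  }
  clades <- NULL
  if (!is.null(species_tree)) {
    if (is.character(species_tree)) {
      species_tree <- if (file.exists(species_tree))
        ape::read.tree(species_tree) else ape::read.tree(text = species_tree)
    }
    keep <- intersect(species_tree$tip.label, species)
    if (length(keep) < length(species)) {
      stop("species tree is missing target species")
    }
    if (length(species_tree$tip.label) > length(species)) {
      species_tree <- ape::keep.tip(species_tree, species)
    }
    clades <- lapply(tree_clades(species_tree), sort)
  }
  rows <- lapply(anchors, function(a) {
    sub <- calls[calls$anchor_gene == a, ]
    lost <- sort(sub$species[sub$call %in% c("decayed", "deleted")])
    cluster <- if (length(lost) == 0) "retained_all"
               else if (any(sub$call == "decayed")) "decayed_cluster"
               else "deleted_cluster"
    cryptic <- if (is.null(clades)) NA
               else if (length(lost) == 0) FALSE
               else !any(vapply(clades, function(cl) identical(cl, lost),
                                logical(1)))
    data.frame(anchor_gene = a,
               bin = if (length(lost) == 0) "none"
                     else paste(lost, collapse = ","),
               n_lost = length(lost), cryptic = cryptic, cluster = cluster)
  })
  do.call(rbind, rows)
}

#' Summarize loss calls and patterns
#'
#' @param patterns Output of [classify_patterns()].
#' @param calls The per-locus call data frame.
#' @return List with `per_species` (call-by-species count matrix),
#'   `clusters` (named counts of retained_all / decayed_cluster /
#'   deleted_cluster) and `bins` (pattern-bin histogram with cryptic flag).
#' @export
summarize_events <- function(patterns, calls) {
  per_species <- table(factor(calls$call,
                              levels = c("retained", "decayed", "deleted",
                                         "non_informative")),
                       calls$species)
  clusters <- table(factor(patterns$cluster,
                           levels = c("retained_all", "decayed_cluster",
                                      "deleted_cluster")))
  cnt <- table(patterns$bin)
  bins <- data.frame(bin = names(cnt),
                     cryptic = patterns$cryptic[match(names(cnt),
                                                      patterns$bin)],
                     n = as.integer(cnt))
  list(per_species = unclass(per_species),
       clusters = stats::setNames(as.integer(clusters), names(clusters)),
       bins = bins[order(-bins$n), ])
}

#' Chi-square goodness-of-fit test against the uniform distribution
#'
#' Wraps [stats::chisq.test()] with equal expected cell probabilities:
#' `statistic = sum((O - E)^2 / E)` with `E = total / ncells`, `df =
#' ncells - 1`, upper-tail p-value. No continuity correction.
#'
#' @param observed Non-negative integer vector, length >= 2, total > 0.
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' chisq_uniform(c(8, 2))  # statistic 3.6, df 1
#' @export
chisq_uniform <- function(observed) {
  if (length(observed) < 2) stop("need at least 2 cells")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (sum(observed) == 0) stop("all-zero observed counts")
  ht <- suppressWarnings(stats::chisq.test(observed))
  list(statistic = unname(ht$statistic),
       df = as.integer(unname(ht$parameter)),
       p_value = unname(ht$p.value))
}
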