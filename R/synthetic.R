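## Synthetic inputs with planted ground truth: count matrices whose
## per-group expected counts change linearly with distance-to-LCA (Poisson
## noise), ladder species trees, and toy multi-species genomes sharing
## syntenic gene order with planted retention / decay / deletion events.

#' Build a ladder species tree realizing tip-to-LCA distances
#'
#' Rooted ladder (caterpillar) topology `(s1, (s2, (s3, ...)))` with branch
#' lengths chosen so the path from the root (= LCA of all species) to tip
#' `i` sums to `distances[i]`.
#'
#' @param species Character vector (>= 2).
#' @param distances Positive tip-to-LCA distances, one per species.
#' @return Newick string (terminated by `;`).
#' @examples
#' make_tree(c("A", "B"), c(1, 1))
#' @export
make_tree <- function(species, distances) {
  n <- length(species)
  if (n < 2) stop("need at least 2 species")
  if (length(distances) != n) stop("one distance per species")
  if (any(distances <= 0)) stop("distances must be positive")
  if (n == 2) {
    return(sprintf("(%s:%.15g,%s:%.15g);", species[1], distances[1],
                   species[2], distances[2]))
  }
  delta <- 0.5 * min(distances) / (n - 1)   # internal node depth increment
  depth <- (seq_len(n - 1) - 1) * delta
  if (any(distances[seq_len(n - 1)] <= depth) ||
      distances[n] <= depth[n - 1]) {
    stop("inconsistent distances: tip shallower than its attachment node")
  }
  sub <- sprintf("(%s:%.15g,%s:%.15g)", species[n - 1],
                 distances[n - 1] - depth[n - 1],
                 species[n], distances[n] - depth[n - 1])
  for (j in rev(seq_len(n - 2))) {
    sub <- sprintf("(%s:%.15g,%s:%.15g)", species[j],
                   distances[j] - depth[j], sub, delta)
  }
  paste0(sub, ";")
}

#' Configuration for the synthetic count matrix
#'
#' Defaults emulate a six-species in-group at distances 0.5..5.5 from the
#' LCA with a baseline of 36 copies per group, 2% of groups contracting and
#' 2% expanding at the planted signal size `|beta| * range(d) =
#' 5 * sqrt(baseline_mean)` (five Poisson standard deviations across the
#' distance range). The baseline is large enough that a contracting group's
#' expected count stays positive at the farthest species, so the epsilon
#' floor never distorts the planted linear signal.
#'
#' @param n_groups Number of orthologous groups.
#' @param species Species names.
#' @param distances Per-species distances to the LCA.
#' @param baseline_mean Expected copies per group at distance 0 (> 0).
#' @param planted Data frame with columns `fraction` and `beta` (slope per
#'   unit distance); fractions must sum to <= 1.
#' @param epsilon Floor for the Poisson mean where the linear predictor
#'   goes negative.
#' @param seed RNG seed.
#' @return List of class `count_synth_config`.
#' @export
count_synth_config <- function(n_groups = 1000L,
                               species = c("A", "B", "C", "D", "E", "F"),
                               distances = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5),
                               baseline_mean = 36,
                               planted = NULL,
                               epsilon = 0.01, seed = 1L) {
  if (baseline_mean <= 0) stop("baseline_mean must be > 0")
  if (length(distances) != length(species)) {
    stop("one distance per species")
  }
  if (is.null(planted)) {
    b <- 5 * sqrt(baseline_mean) / diff(range(distances))
    planted <- data.frame(fraction = c(0.02, 0.02), beta = c(-b, b))
  }
  if (sum(planted$fraction) > 1) stop("planted fractions must sum to <= 1")
  structure(list(n_groups = as.integer(n_groups), species = species,
                 distances = as.numeric(distances),
                 baseline_mean = baseline_mean, planted = planted,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "count_synth_config")
}

#' Generate a count matrix with planted slope effects
#'
#' Counts are `Poisson(max(epsilon, baseline_mean + beta_g * d_s))` with
#' `beta_g = 0` for neutral groups and the planted slope for affected
#' groups (assigned to uniformly random groups).
#'
#' @param config A [count_synth_config()].
#' @return List with `counts` (group x species integer matrix), `truth`
#'   (data frame `group_id`, `beta`) and `distances` (named vector).
#' @export
make_count_matrix <- function(config = count_synth_config()) {
  set.seed(config$seed)
  G <- config$n_groups
  ids <- sprintf("OG%05d", seq_len(G))
  beta <- numeric(G)
  pool <- sample.int(G)   # random assignment of planted groups
  taken <- 0L
  for (i in seq_len(nrow(config$planted))) {
    k <- round(config$planted$fraction[i] * G)
    if (k > 0) {
      beta[pool[taken + seq_len(k)]] <- config$planted$beta[i]
      taken <- taken + k
    }
  }
  mu <- pmax(config$epsilon,
             outer(beta, config$distances) + config$baseline_mean)
  counts <- matrix(stats::rpois(length(mu), mu), nrow = G,
                   dimnames = list(ids, config$species))
  list(counts = counts,
       truth = data.frame(group_id = ids, beta = beta),
       distances = stats::setNames(config$distances, config$species))
}

#' Configuration for the toy syntenic genomes
#'
#' Defaults: 6 species (the first is the anchor), 2 chromosomes of 30
#' genes, 300-codon genes, 200-nt intergenic spacers — large enough to
#' exercise every code path, small enough for seconds-scale runs. Planted
#' loss events are sampled per (gene, species); odd-indexed genes and the
#' last gene of each chromosome are constitutive (retained in every
#' species) so each planted loss keeps annotated syntenic flanks at any
#' window >= 1.
#'
#' @param species Species names; `species[1]` is the anchor.
#' @param n_chromosomes,genes_per_chromosome,gene_length,intergenic_length
#'   Genome geometry (`gene_length` in codons, start and stop included).
#' @param neutral_rate Per-site substitution probability applied to each
#'   derived species (0 = identical copies).
#' @param event_probs Named probabilities for `retain`, `decay`, `delete`
#'   at event-bearing genes.
#' @param remnant_fraction Fraction of the gene body left in place by a
#'   decay event, in (0, 1).
#' @param n_frameshifts,n_stops Single-nucleotide deletions / premature
#'   stop codons injected into each decay remnant.
#' @param events Optional explicit event table (`anchor_gene`, `species`,
#'   `event`) overriding the sampler.
#' @param seed RNG seed.
#' @return List of class `genome_synth_config`.
#' @export
genome_synth_config <- function(species = c("anc", "sp1", "sp2", "sp3",
                                            "sp4", "sp5"),
                                n_chromosomes = 2L,
                                genes_per_chromosome = 30L,
                                gene_length = 300L,
                                intergenic_length = 200L,
                                neutral_rate = 0,
                                event_probs = c(retain = 0.6, decay = 0.25,
                                                delete = 0.15),
                                remnant_fraction = 0.6,
                                n_frameshifts = 2L, n_stops = 2L,
                                events = NULL, seed = 1L) {
  if (length(species) < 2) stop("need an anchor plus >= 1 target species")
  if (remnant_fraction <= 0 || remnant_fraction >= 1) {
    stop("remnant_fraction must lie in (0, 1)")
  }
  if (abs(sum(event_probs) - 1) > 1e-8) stop("event_probs must sum to 1")
  if (neutral_rate < 0 || neutral_rate > 0.5) {
    stop("neutral_rate must lie in [0, 0.5]")
  }
  structure(list(species = species,
                 n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 gene_length = as.integer(gene_length),
                 intergenic_length = as.integer(intergenic_length),
                 neutral_rate = neutral_rate, event_probs = event_probs,
                 remnant_fraction = remnant_fraction,
                 n_frameshifts = as.integer(n_frameshifts),
                 n_stops = as.integer(n_stops), events = events,
                 seed = as.integer(seed)),
            class = "genome_synth_config")
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n) {
  # stop-free codons
  out <- character(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    cand <- paste0(sample(BASES, length(need), TRUE),
                   sample(BASES, length(need), TRUE),
                   sample(BASES, length(need), TRUE))
    out[need] <- cand
    need <- need[cand %in% STOP_CODONS]
  }
  out
}

random_orf <- function(n_codons) {
  paste0("ATG", paste(random_codons(n_codons - 2L), collapse = ""),
         sample(STOP_CODONS, 1L))
}

random_dna <- function(n) paste(sample(BASES, n, TRUE), collapse = "")

mutate_dna <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0) {
    for (i in hit) {
      chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
    }
  }
  paste(chars, collapse = "")
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

decay_remnant <- function(coding_seq, remnant_fraction, n_frameshifts,
                          n_stops) {
  L <- nchar(coding_seq)
  keep <- max(3L, ceiling(remnant_fraction * L))
  rem <- substr(coding_seq, 1L, keep)
  n_codons <- floor(nchar(rem) / 3)
  if (n_stops > 0 && n_codons > 3) {
    at <- sample(2:(n_codons - 1), min(n_stops, n_codons - 2L))
    for (cd in at) {
      substr(rem, 3L * (cd - 1L) + 1L, 3L * cd) <- sample(STOP_CODONS, 1L)
    }
  }
  if (n_frameshifts > 0 && nchar(rem) > n_frameshifts + 2L) {
    chars <- strsplit(rem, "", fixed = TRUE)[[1]]
    drop <- sample(2:(length(chars) - 1L), n_frameshifts)
    rem <- paste(chars[-drop], collapse = "")
  }
  rem
}

#' Sample a planted event table
#'
#' Odd-indexed genes (within each chromosome) and the last gene of each
#' chromosome are constitutive: retained in every species. The remaining
#' event-bearing genes receive an independent event per target species
#' drawn from `event_probs`.
#'
#' @param gene_index Data frame with `anchor_gene` and `index_in_chrom`
#'   and `is_last`.
#' @param targets Target species names.
#' @param event_probs Named `retain`/`decay`/`delete` probabilities.
#' @return Data frame `anchor_gene`, `species`, `event`.
#' @keywords internal
sample_event_table <- function(gene_index, targets, event_probs) {
  rows <- list()
  for (i in seq_len(nrow(gene_index))) {
    bearing <- gene_index$index_in_chrom[i] %% 2L == 0L &&
      !gene_index$is_last[i]
    ev <- if (bearing) {
      sample(names(event_probs), length(targets), TRUE, prob = event_probs)
    } else {
      rep("retain", length(targets))
    }
    rows[[i]] <- data.frame(anchor_gene = gene_index$anchor_gene[i],
                            species = targets, event = ev)
  }
  do.call(rbind, rows)
}

#' Generate toy syntenic genomes with planted loss events
#'
#' An anchor genome of random ORFs separated by random intergenic spacers
#' is copied into each derived species with gene order preserved. Each copy
#' receives neutral per-site substitutions, then its planted event:
#' \emph{retain} keeps the gene annotated; \emph{decay} truncates the gene
#' body to `remnant_fraction`, injects premature stops and frameshifts,
#' leaves the remnant in the DNA but removes the gene from the annotation
#' and ortholog table; \emph{delete} excises the locus entirely, splicing
#' the flanking spacers. The ortholog table lists surviving annotated
#' genes grouped by anchor ancestry.
#'
#' @param config A [genome_synth_config()].
#' @return List with `genomes` (named list of [genome_annotation()]),
#'   `table` (ortholog table), `truth` (data frame `anchor_gene`,
#'   `species`, `event`), `tree` (Newick over the target species),
#'   `anchor_species`, and `config`.
#' @export
make_toy_genomes <- function(config = genome_synth_config()) {
  set.seed(config$seed)
  anchor <- config$species[1]
  targets <- config$species[-1]
  C <- config$n_chromosomes
  Gc <- config$genes_per_chromosome
  glen_nt <- 3L * config$gene_length

  # --- anchor genome -------------------------------------------------
  gene_meta <- list()   # per gene: id, chrom, index, strand, coding seq
  spacers <- list()     # per chrom: Gc + 1 spacers
  gid <- 0L
  for (ch in seq_len(C)) {
    spacers[[ch]] <- replicate(Gc + 1L, random_dna(config$intergenic_length))
    for (j in seq_len(Gc)) {
      gid <- gid + 1L
      gene_meta[[gid]] <- list(
        gene = sprintf("g%03d", gid), chrom = sprintf("chr%d", ch),
        index_in_chrom = j, is_last = (j == Gc),
        strand = sample(c("+", "-"), 1L),
        coding = random_orf(config$gene_length))
    }
  }
  meta <- do.call(rbind, lapply(gene_meta, function(m) {
    data.frame(anchor_gene = m$gene, chrom = m$chrom,
               index_in_chrom = m$index_in_chrom, is_last = m$is_last,
               strand = m$strand)
  }))
  coding <- vapply(gene_meta, `[[`, character(1), "coding")
  names(coding) <- meta$anchor_gene

  events <- config$events
  if (is.null(events)) {
    events <- sample_event_table(meta, targets, config$event_probs)
  } else {
    bad <- !(events$anchor_gene %in% meta$anchor_gene) |
           !(events$species %in% targets)
    if (any(bad)) stop("planted event on nonexistent gene or species")
    # pairs not listed default to retain
    full <- expand.grid(anchor_gene = meta$anchor_gene, species = targets,
                        stringsAsFactors = FALSE)
    full$event <- "retain"
    key <- paste(events$anchor_gene, events$species)
    m <- match(paste(full$anchor_gene, full$species), key)
    full$event[!is.na(m)] <- events$event[m[!is.na(m)]]
    events <- full
  }

  build_species <- function(sp) {
    is_anchor <- sp == anchor
    rows <- list(); seqs <- character(C)
    prefix <- if (is_anchor) "" else paste0(sp, "_")
    for (ch in seq_len(C)) {
      chrom <- sprintf("chr%d", ch)
      idx <- which(meta$chrom == chrom)
      pieces <- character(0)
      pos <- 0L
      mut <- function(s) if (is_anchor) s else mutate_dna(s, config$neutral_rate)
      add <- function(s) {
        pieces[[length(pieces) + 1L]] <<- s
        pos <<- pos + nchar(s)
      }
      add(mut(spacers[[ch]][1L]))
      for (j in seq_along(idx)) {
        g <- meta$anchor_gene[idx[j]]
        ev <- if (is_anchor) "retain"
              else events$event[events$anchor_gene == g &
                                events$species == sp]
        body <- mut(coding[[g]])
        if (ev == "retain") {
          ins <- if (meta$strand[idx[j]] == "-") revcomp_chr(body) else body
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = paste0(prefix, g), chrom = chrom,
            start = pos + 1L, end = pos + nchar(ins),
            strand = meta$strand[idx[j]], anchor_gene = g)
          add(ins)
        } else if (ev == "decay") {
          rem <- decay_remnant(body, config$remnant_fraction,
                               config$n_frameshifts, config$n_stops)
          ins <- if (meta$strand[idx[j]] == "-") revcomp_chr(rem) else rem
          add(ins)                                   # unannotated remnant
        }                                            # delete: nothing
        add(mut(spacers[[ch]][j + 1L]))
      }
      seqs[ch] <- paste(pieces, collapse = "")
    }
    names(seqs) <- sprintf("chr%d", seq_len(C))
    genes <- do.call(rbind, rows)
    list(annot = genome_annotation(
           genes[, c("gene_id", "chrom", "start", "end", "strand")],
           Biostrings::DNAStringSet(seqs)),
         membership = genes[, c("gene_id", "anchor_gene")])
  }

  genomes <- list(); membership <- list()
  for (sp in config$species) {
    built <- build_species(sp)
    genomes[[sp]] <- built$annot
    membership[[sp]] <- cbind(built$membership, species = sp)
  }
  mem <- do.call(rbind, membership)
  groups <- stats::setNames(sprintf("OG%04d", seq_len(nrow(meta))),
                            meta$anchor_gene)
  table <- as_ortholog_table(data.frame(
    group_id = unname(groups[mem$anchor_gene]),
    species = mem$species, gene_id = mem$gene_id))

  tree <- if (length(targets) >= 2) make_tree(targets, seq_along(targets))
          else NULL
  list(genomes = genomes, table = table,
       truth = events[order(events$anchor_gene, events$species), ],
       tree = tree, anchor_species = anchor, groups = groups,
       config = config)
}

#' Write toy genomes and companions to disk
#'
#' FASTA (\pkg{Biostrings}) and GFF3 (\pkg{rtracklayer}) per species, the
#' ortholog table as TSV, the planted truth as JSON, and the target
#' species tree as Newick.
#'
#' @param toy Output of [make_toy_genomes()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_genomes <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sp in names(toy$genomes)) {
    an <- toy$genomes[[sp]]
    fa <- file.path(dir, paste0(sp, ".fasta"))
    Biostrings::writeXStringSet(an$seq, fa)
    gff <- file.path(dir, paste0(sp, ".gff3"))
    gr <- GenomicRanges::GRanges(
      seqnames = an$genes$chrom,
      ranges = IRanges::IRanges(an$genes$start, an$genes$end),
      strand = an$genes$strand)
    gr$type <- "gene"
    gr$ID <- an$genes$gene_id
    rtracklayer::export(gr, gff, format = "gff3")
    files <- c(files, fa, gff)
  }
  tab <- file.path(dir, "orthologs.tsv")
  utils::write.table(toy$table, tab, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- file.path(dir, "planted_truth.json")
  jsonlite::write_json(toy$truth, truth, dataframe = "rows")
  out <- c(files, tab, truth)
  if (!is.null(toy$tree)) {
    nwk <- file.path(dir, "species_tree.nwk")
    writeLines(toy$tree, nwk)
    out <- c(out, nwk)
  }
  invisible(out)
}
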