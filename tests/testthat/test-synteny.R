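# A tiny hand-built two-species fixture used across the synteny tests:
# anchor genome with 6 genes on one chromosome plus 1 on a second scaffold.
make_fixture <- function() {
  set.seed(314)
  genes <- lapply(1:7, function(i) {
    paste0("ATG", paste(replicate(60, {
      repeat { cd <- random_dna_str(3); if (!cd %in% c("TAA", "TAG", "TGA")) break }
      cd
    }), collapse = ""), "TAA")
  })
  spacer <- function() random_dna_str(50)
  build <- function(gene_seqs, ids, chrom) {
    pieces <- spacer(); rows <- list(); pos <- nchar(pieces)
    for (i in seq_along(gene_seqs)) {
      rows[[i]] <- data.frame(gene_id = ids[i], chrom = chrom,
                              start = pos + 1L,
                              end = pos + nchar(gene_seqs[[i]]),
                              strand = "+")
      sp <- spacer()
      pieces <- paste0(pieces, gene_seqs[[i]], sp)
      pos <- pos + nchar(gene_seqs[[i]]) + nchar(sp)
    }
    list(genes = do.call(rbind, rows), seq = pieces)
  }
  anc1 <- build(genes[1:6], paste0("a", 1:6), "chr1")
  anc2 <- build(genes[7], "a7", "scaf9")
  anchor <- genome_annotation(
    rbind(anc1$genes, anc2$genes),
    Biostrings::DNAStringSet(c(chr1 = anc1$seq, scaf9 = anc2$seq)))
  # target: a4 decayed (truncated remnant kept, unannotated), a2 deleted
  remnant <- substr(genes[[4]], 1, 110)
  tg_seqs <- list(genes[[1]], NULL, genes[[3]], remnant, genes[[5]], genes[[6]])
  pieces <- spacer(); rows <- list(); pos <- nchar(pieces)
  ann <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  for (i in 1:6) {
    if (is.null(tg_seqs[[i]])) next
    if (ann[i]) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = paste0("t", i), chrom = "chr1", start = pos + 1L,
        end = pos + nchar(tg_seqs[[i]]), strand = "+")
    }
    sp <- spacer()
    pieces <- paste0(pieces, tg_seqs[[i]], sp)
    pos <- pos + nchar(tg_seqs[[i]]) + nchar(sp)
  }
  target <- genome_annotation(do.call(rbind, rows),
                              Biostrings::DNAStringSet(c(chr1 = pieces)))
  tab <- as_ortholog_table(data.frame(
    group_id = paste0("OG", c(1:7, c(1, 3, 5, 6))),
    species = c(rep("anc", 7), rep("tgt", 4)),
    gene_id = c(paste0("a", 1:7), paste0("t", c(1, 3, 5, 6)))))
  list(anchor = anchor, target = target, table = tab)
}

fx <- make_fixture()

test_that("anchor selection keeps chromosome-placed contracting genes", {
  sel <- select_anchor_loci(fx$table, fx$anchor, paste0("OG", c(2, 4, 7)),
                            chromosome_ids = "chr1", anchor_species = "anc")
  expect_setequal(sel$selected, c("a2", "a4"))
  expect_identical(sel$filtered$gene_id, "a7")
  expect_identical(sel$filtered$reason, "unplaced_scaffold")
  expect_error(select_anchor_loci(fx$table, fx$anchor, "OG99", "chr1", "anc"),
               "unknown group")
  empty <- select_anchor_loci(fx$table, fx$anchor, character(0), "chr1", "anc")
  expect_length(empty$selected, 0)
})

test_that("neighborhoods truncate at chromosome ends", {
  mid <- build_neighborhood("a3", fx$anchor, window = 2)
  expect_identical(mid$upstream, c("a2", "a1"))     # nearest first
  expect_identical(mid$downstream, c("a4", "a5"))
  first <- build_neighborhood("a1", fx$anchor, window = 2)
  expect_length(first$upstream, 0)
  expect_identical(first$downstream, c("a2", "a3"))
  wide <- build_neighborhood("a3", fx$anchor, window = 50)
  expect_identical(wide$upstream, c("a2", "a1"))
  expect_identical(wide$downstream, c("a4", "a5", "a6"))
  expect_error(build_neighborhood("zz", fx$anchor, 2), "not in annotation")
})

test_that("neighborhood mapping bounds an interval between innermost flanks", {
  nb <- build_neighborhood("a4", fx$anchor, window = 2)
  iv <- map_neighborhood(nb, fx$table, fx$target, "anc", "tgt")
  expect_identical(iv$scaffold, "chr1")
  expect_identical(iv$left_gene, "t3")
  expect_identical(iv$right_gene, "t5")
  g <- fx$target$genes
  expect_identical(iv$start, g$start[g$gene_id == "t3"])
  expect_identical(iv$end, g$end[g$gene_id == "t5"])
  # orthologs absent in target -> no interval
  tab2 <- fx$table[fx$table$species == "anc", ]
  expect_null(map_neighborhood(nb, as_ortholog_table(tab2), fx$target,
                               "anc", "tgt"))
  # flanks split across scaffolds -> no interval
  g2 <- fx$target$genes
  g2$chrom[g2$gene_id %in% c("t5", "t6")] <- "chr2"
  split_target <- genome_annotation(
    g2, Biostrings::DNAStringSet(c(chr1 = as.character(fx$target$seq[[1]]),
                                   chr2 = as.character(fx$target$seq[[1]]))))
  expect_null(map_neighborhood(nb, fx$table, split_target, "anc", "tgt"))
})

test_that("locus calls follow the retained / decayed / deleted / NI rules", {
  a4 <- gene_sequence(fx$anchor, "a4")
  a2 <- gene_sequence(fx$anchor, "a2")
  # retained short-circuits the search
  expect_identical(call_locus(a4, NULL, TRUE)$call, "retained")
  # no interval -> non-informative
  expect_identical(call_locus(a4, NULL, FALSE)$call, "non_informative")
  # planted decay: remnant inside the mapped interval
  nb4 <- build_neighborhood("a4", fx$anchor, window = 2)
  iv <- map_neighborhood(nb4, fx$table, fx$target, "anc", "tgt")
  subject <- as.character(Biostrings::subseq(fx$target$seq[[iv$scaffold]],
                                             iv$start, iv$end))
  res <- call_locus(a4, subject, FALSE)
  expect_identical(res$call, "decayed")
  expect_lt(res$best_hit$evalue, 1e-5)
  # planted deletion: locus excised, flanks intact
  nb2 <- build_neighborhood("a2", fx$anchor, window = 2)
  iv2 <- map_neighborhood(nb2, fx$table, fx$target, "anc", "tgt")
  subject2 <- as.character(Biostrings::subseq(fx$target$seq[[iv2$scaffold]],
                                              iv2$start, iv2$end))
  expect_identical(call_locus(a2, subject2, FALSE)$call, "deleted")
  expect_error(call_locus("", NULL, FALSE), "empty")
})

test_that("tightening the E-value threshold never turns deleted into decayed", {
  a4 <- gene_sequence(fx$anchor, "a4")
  nb4 <- build_neighborhood("a4", fx$anchor, window = 2)
  iv <- map_neighborhood(nb4, fx$table, fx$target, "anc", "tgt")
  subject <- as.character(Biostrings::subseq(fx$target$seq[[iv$scaffold]],
                                             iv$start, iv$end))
  calls <- vapply(c(1e-2, 1e-5, 1e-20, 1e-60),
                  function(th) call_locus(a4, subject, FALSE, th)$call,
                  character(1))
  decayed <- calls == "decayed"
  # once the call drops to deleted it stays deleted at tighter thresholds
  expect_true(all(diff(decayed) <= 0))
})

test_that("pattern bins, cryptic flags and clusters follow the tree", {
  tree <- ape::read.tree(text = "(G,(P,(Y,(E,V))));")
  mk_calls <- function(lost, mech = "decayed") {
    do.call(rbind, lapply(c("G", "P", "Y", "E", "V"), function(sp) {
      data.frame(anchor_gene = "g1", species = sp,
                 call = if (sp %in% lost) mech else "retained")
    }))
  }
  p1 <- classify_patterns(mk_calls(c("Y", "E", "V")), tree)
  expect_false(p1$cryptic)                       # one clade
  expect_identical(p1$cluster, "decayed_cluster")
  p2 <- classify_patterns(mk_calls(c("G", "E")), tree)
  expect_true(p2$cryptic)                        # two independent events
  p3 <- classify_patterns(mk_calls(character(0)), tree)
  expect_false(p3$cryptic)
  expect_identical(p3$cluster, "retained_all")
  expect_identical(p3$bin, "none")
  p4 <- classify_patterns(mk_calls(c("E", "V"), mech = "deleted"), tree)
  expect_identical(p4$cluster, "deleted_cluster")
  # a single decay among deletions dominates the cluster label
  mixed <- mk_calls(c("E", "V"), mech = "deleted")
  mixed$call[mixed$species == "E"] <- "decayed"
  expect_identical(classify_patterns(mixed, tree)$cluster, "decayed_cluster")
  # incomplete call sets are rejected (one anchor lacks one species)
  two <- rbind(mk_calls("G"), within(mk_calls("P"), anchor_gene <- "g2"))
  expect_error(classify_patterns(two[-1, ], tree), "every")
})

test_that("cryptic flags agree with brute-force clade enumeration", {
  tree <- ape::read.tree(text = "(G,(P,(Y,(E,V))));")
  species <- c("G", "P", "Y", "E", "V")
  set.seed(99)
  for (r in 1:40) {
    lost <- species[runif(5) < 0.4]
    calls <- do.call(rbind, lapply(species, function(sp) {
      data.frame(anchor_gene = "g", species = sp,
                 call = if (sp %in% lost) "deleted" else "retained")
    }))
    got <- classify_patterns(calls, tree)$cryptic
    expect_identical(got, !oracle_is_clade(tree, lost))
  }
})

test_that("event summaries partition the loci", {
  calls <- expand.grid(anchor_gene = paste0("g", 1:10),
                       species = c("s1", "s2"), stringsAsFactors = FALSE)
  calls$call <- "retained"
  calls$call[calls$anchor_gene == "g1" & calls$species == "s1"] <- "decayed"
  calls$call[calls$anchor_gene == "g2" & calls$species == "s2"] <- "deleted"
  pat <- classify_patterns(calls, NULL)
  s <- summarize_events(pat, calls)
  expect_identical(unname(colSums(s$per_species)), c(10, 10))
  expect_identical(unname(s$clusters),
                   c(8L, 1L, 1L))   # retained_all, decayed, deleted
  expect_identical(sum(s$bins$n), 10L)
})

test_that("chi-square GOF against uniform matches hand computation", {
  res <- chisq_uniform(c(8, 2))
  expect_equal(res$statistic, 3.6)   # (8-5)^2/5 + (2-5)^2/5
  expect_identical(res$df, 1L)
  flat <- chisq_uniform(c(5, 5))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_identical(chisq_uniform(c(10, 10, 10))$df, 2L)
  expect_error(chisq_uniform(c(0, 0)), "all-zero")
  expect_error(chisq_uniform(5), "at least 2")
})
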