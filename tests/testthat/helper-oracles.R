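# Independent brute-force oracles used by the property tests. Each is
# written against the mathematical definition, not the package's code
# path.

RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

# Exact two-sided rank-sum p by direct enumeration over label
# assignments (smaller tail of group A's rank-sum distribution,
# doubled).
oracle_ranksum_p <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a)
  n <- length(r)
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  assignments <- utils::combn(n, na)
  uas <- apply(assignments, 2, function(i) sum(r[i]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(uas <= ua + 1e-9), mean(uas >= ua - 1e-9)))
}

# LCA oracle: deepest common prefix of best-hit lineages, then
# threshold lifting (species >= 95, genus >= 85, phylum >= 65).
oracle_lca <- function(hits, lineages, tie_tol = 0) {
  best <- hits[hits$bitscore >= max(hits$bitscore) - tie_tol, , drop = FALSE]
  max_id <- max(best$pct_identity)
  cap <- if (max_id >= 95) 7 else if (max_id >= 85) 6 else if (max_id >= 65) 2 else 0
  if (cap == 0) return(list(rank = "unassigned", lineage = rep(NA_character_, 7)))
  lins <- lapply(best$subject_id, function(s) {
    unlist(lineages[lineages$subject_id == s, RANKS], use.names = FALSE)
  })
  depth <- 0
  for (d in 1:7) {
    vals <- vapply(lins, `[`, character(1), d)
    if (anyNA(vals) || length(unique(vals)) > 1) break
    depth <- d
  }
  depth <- min(depth, cap)
  lineage <- rep(NA_character_, 7)
  if (depth > 0) lineage[1:depth] <- lins[[1]][1:depth]
  list(rank = if (depth == 0) "unassigned" else RANKS[depth], lineage = lineage)
}

# Unweighted UniFrac oracle by explicit enumeration of root-to-leaf
# branch sets: for every edge decide membership by listing the leaves
# below it (via the tree's node paths), then apply the definition.
oracle_unifrac_pair <- function(tree, present_a, present_b) {
  ntip <- length(tree$tip.label)
  leaves_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, leaves_below))
  }
  uniq <- 0
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    below <- leaves_below(tree$edge[e, 2])
    in_a <- any(below %in% present_a)
    in_b <- any(below %in% present_b)
    if (in_a || in_b) total <- total + tree$edge.length[e]
    if (xor(in_a, in_b)) uniq <- uniq + tree$edge.length[e]
  }
  if (total == 0) 0 else uniq / total
}

# Two-sided Fisher p by full enumeration of 2x2 tables with fixed
# margins, summing hypergeometric probabilities <= the observed one.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Deterministic small lineage fixture: two phyla, nested genera.
fixture_lineages <- function() {
  tibble::tribble(
    ~subject_id, ~domain, ~phylum, ~class, ~order, ~family, ~genus, ~species,
    "g1", "Bacteria", "Proteobacteria", "Gammaproteobacteria", "Pseudomonadales",
    "Pseudomonadaceae", "Pseudomonas", "Pseudomonas stutzeri",
    "g2", "Bacteria", "Proteobacteria", "Gammaproteobacteria", "Pseudomonadales",
    "Pseudomonadaceae", "Pseudomonas", "Pseudomonas alcaligenes",
    "g3", "Bacteria", "Proteobacteria", "Betaproteobacteria", "Burkholderiales",
    "Comamonadaceae", "Acidovorax", "Acidovorax sp.",
    "g4", "Bacteria", "Deinococcus-Thermus", "Deinococci", "Thermales",
    "Thermaceae", "Thermus", "Thermus thermophilus"
  )
}

hit_row <- function(query = "q1", subject, identity, bitscore = 100,
                    evalue = 1e-30, aln = 900, slen = 1000) {
  tibble::tibble(query_id = query, subject_id = subject,
                 pct_identity = identity, aln_length = aln,
                 evalue = evalue, bitscore = bitscore, subject_length = slen)
}

# A nested lineage table over `n` reference subjects (two species per
# genus, two genera per family, ...) for the LCA property test.
nested_lineages <- function(n) {
  i <- seq_len(n)
  tibble::tibble(
    subject_id = paste0("s", i),
    domain = "Bacteria",
    phylum = paste0("P", (i - 1) %/% 32 + 1),
    class = paste0("C", (i - 1) %/% 16 + 1),
    order = paste0("O", (i - 1) %/% 8 + 1),
    family = paste0("F", (i - 1) %/% 4 + 1),
    genus = paste0("G", (i - 1) %/% 2 + 1),
    species = paste0("S", i)
  )
}
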