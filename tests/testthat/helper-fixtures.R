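# Fixture builders shared across the suite; everything is generated in code.

# a protein with n planted 21-residue hydrophobic stretches separated by
# hydrophilic spacers (mirrors the generator's architecture)
mkTmProteinFix <- function(nStretch, stretch = strrep("I", 21),
                           spacer = strrep("D", 25)) {
  paste0(spacer, paste(rep(paste0(stretch, spacer), nStretch), collapse = ""))
}

mkNbdProteinFix <- function() paste0(strrep("N", 40), "GPSGSGKST",
                                     strrep("N", 60))

mkDecoyProteinFix <- function(len = 120) strrep("E", len)

# the standard fermentation sampling grid
fermDays <- c(0.75, 2, 3, 4, 6, 8)

# noise-free logistic titer on the standard grid
fixtureProduction <- function(plateau = 2000)
  simulateProductionCurve(fermDays, plateau, seed = 1, noiseSd = 0)

# a small random additive tree (unrooted, positive branch lengths) plus
# its cophenetic distance matrix; uses the current RNG stream
randomAdditiveCase <- function(nTaxa) {
  tr <- ape::unroot(ape::rtree(nTaxa,
                               tip.label = sprintf("T%02d", seq_len(nTaxa))))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# brute-force least-squares fit of a 4-taxon distance matrix to one
# unrooted topology; returns the residual sum of squares. Topology is
# given as the pair grouped together, e.g. c("A","B").
ls4ResidualFix <- function(dm, pair) {
  taxa <- rownames(dm)
  grp1 <- pair
  grp2 <- setdiff(taxa, pair)
  ord <- c(grp1, grp2)   # edges: a,b to grp1; c,d to grp2; e internal
  pairs <- t(combn(ord, 2))
  X <- matrix(0, nrow(pairs), 5)
  y <- numeric(nrow(pairs))
  limb <- stats::setNames(1:4, ord)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    X[r, limb[[i]]] <- 1
    X[r, limb[[j]]] <- 1
    sameSide <- (i %in% grp1) == (j %in% grp1)
    if (!sameSide) X[r, 5] <- 1
    y[r] <- dm[i, j]
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}
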