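# Independent oracles used across the test files.  These deliberately
# re-derive results with different algorithms/code paths than the
# package internals they check.

# Global affine-gap alignment score by explicit Gotoh dynamic
# programming, matching the pairwiseAlignment convention that a gap of
# length L costs open + L * ext.
gotoh_score <- function(a, b, open = 10, ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # match state
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force non-bonded pair-sum energy with the same physics as the
# package model, written as plain double loops over atoms.
naive_energy <- function(structure, model = energy_model()) {
  n <- nrow(structure)
  lj <- subsites:::lj_params(structure$element)
  q <- subsites:::atom_partial_charge(structure$res_name, structure$atom)
  hb <- subsites:::hb_capable(structure)
  xyz <- atom_coords(structure)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_chain <- structure$chain[i] == structure$chain[j]
      if (same_chain && structure$ins[i] == structure$ins[j] &&
          abs(structure$res_seq[i] - structure$res_seq[j]) <= 1) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r >= model$cutoff) next
      rmin <- lj$rmin[i] + lj$rmin[j]
      eps <- sqrt(lj$eps[i] * lj$eps[j])
      s6 <- (rmin / r)^6
      total <- total + model$w_lj * eps * (s6^2 - 2 * s6)
      total <- total + model$w_coulomb * 332 * q[i] * q[j] /
        (model$dielectric * r^2)
      if ((hb$donor[i] && hb$acceptor[j]) || (hb$acceptor[i] && hb$donor[j])) {
        total <- total - model$w_hbond * max(0, 1 - abs(r - 2.9) / 0.6)
      }
    }
  }
  total
}

# Independent neighbourhood-signature similarity for small chemical
# graphs: enumerates, for every atom, the multiset of (element, bond
# order) walks up to the radius by breadth-first traversal, coded
# differently from the package fingerprint.
walk_signatures <- function(graph, radius = 2) {
  n <- length(graph$elements)
  if (n == 0) return(character(0))
  adj <- vector("list", n)
  if (nrow(graph$bonds) > 0) {
    for (k in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds[k, 1]; j <- graph$bonds[k, 2]
      o <- graph$bonds[k, 3]
      adj[[i]] <- c(adj[[i]], list(c(j, o)))
      adj[[j]] <- c(adj[[j]], list(c(i, o)))
    }
  }
  deg <- vapply(adj, length, integer(1))
  token <- paste0(graph$elements, deg)
  sigs <- character(0)
  for (start in seq_len(n)) {
    # depth-limited non-backtracking walks over element/degree tokens
    level <- list(list(node = start, prev = 0, path = token[start]))
    sigs <- c(sigs, token[start])
    for (r in seq_len(radius)) {
      nxt <- list()
      for (st in level) {
        for (nb in adj[[st$node]]) {
          if (nb[1] == st$prev) next
          p <- paste0(st$path, "~", nb[2], "~", token[nb[1]])
          nxt <- c(nxt, list(list(node = nb[1], prev = st$node, path = p)))
          sigs <- c(sigs, p)
        }
      }
      level <- nxt
    }
  }
  sort(unique(sigs))
}

walk_similarity <- function(g1, g2, radius = 2) {
  s1 <- walk_signatures(g1, radius)
  s2 <- walk_signatures(g2, radius)
  if (length(s1) == 0 && length(s2) == 0) return(1)
  length(intersect(s1, s2)) / length(union(s1, s2))
}

# Average-rank Spearman correlation from first principles.
rank_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# A random proper rotation matrix + translation.
random_rigid_transform <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_dec <- qr(A)
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid <- function(structure, tf) {
  xyz <- atom_coords(structure)
  xyz <- sweep(xyz %*% t(tf$R), 2, tf$t, FUN = "+")
  subsites:::set_atom_coords(structure, xyz)
}

# Minimal two-chain complex used by several geometric tests: one
# protease residue placed at a controlled distance from a peptide.
shift_chain <- function(structure, chain_id, dx = 0, dy = 0, dz = 0) {
  sel <- structure$chain == chain_id
  structure$x[sel] <- structure$x[sel] + dx
  structure$y[sel] <- structure$y[sel] + dy
  structure$z[sel] <- structure$z[sel] + dz
  structure
}

pocket_membership <- function(assignment) {
  out <- dplyr::arrange(
    assignment$pocket_residues[, c("chain", "res_seq", "pocket")],
    pocket, chain, res_seq
  )
  attr(out, "source_id") <- NULL
  tibble::as_tibble(as.data.frame(out))
}
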