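# Hand-built fixtures: small trees whose Brownian covariance (shared path
# lengths) is written out element by element, independent of any tree code.

# three tips: ((A:1,B:1):1,C:2);
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
C3 <- function() {
  matrix(c(2, 1, 0,
           1, 2, 0,
           0, 0, 2), 3, 3, byrow = TRUE,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

# six tips, depth 3: (((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,(E:2,F:2):1);
tree6 <- function() {
  ape::read.tree(text = "(((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,(E:2,F:2):1);")
}
C6 <- function() {
  lab <- c("A", "B", "C", "D", "E", "F")
  C <- matrix(0, 6, 6, dimnames = list(lab, lab))
  diag(C) <- 3
  C["A", "B"] <- C["B", "A"] <- 2
  C["C", "D"] <- C["D", "C"] <- 1.5
  C["E", "F"] <- C["F", "E"] <- 1
  for (i in c("A", "B")) for (j in c("C", "D")) C[i, j] <- C[j, i] <- 1
  C
}

# dense GLS oracle: beta, sigma2 (ML), logLik under covariance C
dense_gls <- function(y, X, C) {
  n <- length(y)
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Ci %*% r) / n
  ll <- -n / 2 * (log(2 * pi * s2) + 1) - 0.5 * determinant(C)$modulus[1]
  list(beta = drop(beta), s2 = s2, logLik = ll)
}

# sorted 1000-value community CTmax sample whose type-7 empirical 10/25/50%
# quantiles are exactly 40/41/42 degC (interpolation positions are tied pairs)
quantile_target_sample <- function() {
  x <- c(seq(38, 40, length.out = 100), 40,
         seq(40.1, 41, length.out = 149), 41,
         seq(41.1, 42, length.out = 249), 42,
         seq(42.1, 47, length.out = 499))
  stopifnot(length(x) == 1000, !is.unsorted(x))
  x
}

# star tree with k tips, unit depth
star_tree <- function(k) {
  ape::read.tree(text = paste0("(", paste0("t", seq_len(k), ":1", collapse = ","), ");"))
}
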