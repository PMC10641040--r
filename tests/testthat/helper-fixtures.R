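## Shared fixtures and independent oracles used across the suite.

## small two-view synthetic dataset
smallSpec <- function(taxa = c(FAA = 2L, FAB = 2L), specimens = 6L,
                      types = "precaudal", n_per_type = 2L,
                      separation = 6, within_sd = 0.02,
                      mirror_fraction = 0, seed = 11, ...) {
  syntheticSpec(taxa_per_family = taxa, specimens_per_taxon = specimens,
                types = types, n_per_type = n_per_type,
                separation = separation, within_sd = within_sd,
                mirror_fraction = mirror_fraction, seed = seed, ...)
}

## apply an independent random rigid + positive-scale nuisance transform to
## every configuration (present landmarks only)
transformSet <- function(x) {
  for (i in seq_along(x@coords)) {
    th <- runif(1, -pi, pi)
    s <- runif(1, 0.5, 2)
    tr <- runif(2, -10, 10)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    pres <- x@present[[i]]
    x@coords[[i]][pres, ] <-
      sweep(s * (x@coords[[i]][pres, , drop = FALSE] %*% t(R)), 2, tr, "+")
  }
  x
}

## brute-force pooled-covariance Gaussian Bayes posteriors (explicit solve
## and density evaluation; independent of the package's chol/backsolve path)
bayesOracle <- function(train, labels, test, uniform_priors = FALSE) {
  cls <- sort(unique(labels))
  p <- ncol(train)
  Sw <- matrix(0, p, p)
  for (cl in cls) {
    r <- train[labels == cl, , drop = FALSE]
    Sw <- Sw + crossprod(sweep(r, 2, colMeans(r)))
  }
  Sw <- Sw / (nrow(train) - length(cls))
  Si <- solve(Sw)
  dens <- sapply(cls, function(cl) {
    m <- colMeans(train[labels == cl, , drop = FALSE])
    pri <- if (uniform_priors) 1 / length(cls) else mean(labels == cl)
    apply(test, 1, function(v)
      pri * exp(-0.5 * drop(t(v - m) %*% Si %*% (v - m))))
  })
  dens <- matrix(dens, nrow = nrow(test))
  colnames(dens) <- cls
  dens / rowSums(dens)
}

## flatten convention used by the package
flat <- function(m) as.vector(t(m))
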