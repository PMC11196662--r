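# shared fixtures, all generated in code

# small labelled data set with a THI-driven logistic ground truth
make_logistic_data <- function(n = 320, beta0 = -22.5, beta1 = 0.30,
                               seed = 1, thi_range = c(55, 95)) {
  set.seed(seed)
  thi <- runif(n, thi_range[1], thi_range[2])
  y <- rbinom(n, 1, plogis(beta0 + beta1 * thi))
  data.frame(thi = thi, abnormal = y)
}

# exhaustive pairwise-concordance AUC (independent oracle)
auc_bruteforce <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# random valid parameter draw for each curve family
random_params <- function(family) {
  tn50 <- runif(1, 40, 110)
  shape <- switch(family,
    lkb = runif(1, 0.01, 0.5),
    logistic = runif(1, 0.05, 1),
    schultheiss = runif(1, 1, 50),
    poisson = runif(1, 0.2, 10))
  abtp_params(family, tn50 = tn50, shape = shape)
}
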