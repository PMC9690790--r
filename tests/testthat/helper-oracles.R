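# Independent oracles for the AHP implementation: dense eigen-decomposition
# of the (unclassed) matrix, used only by the test suite.

eigen_priority <- function(m) {
  e <- eigen(unclass(m))
  k <- which.max(Mod(e$values))
  v <- abs(Re(e$vectors[, k]))
  v / sum(v)
}

eigen_lambda_max <- function(m) {
  max(Re(eigen(unclass(m))$values))
}

eigen_cr <- function(m) {
  n <- nrow(m)
  if (n <= 2) return(0)
  ci <- (eigen_lambda_max(m) - n) / (n - 1)
  ci / random_index(n)
}

random_weights <- function(n) {
  g <- stats::rgamma(n, shape = 2)
  g / sum(g)
}

# The published pot-experiment score table, frozen as (indicator, treatment,
# score-to-2-decimals) for regression.
pot_experiment_expected <- function() {
  long <- rbind(
    data.frame(treatment = "control",
               indicator = c("pH", "SOM", "CEC", "A-N", "A-P", "A-K", "AHM",
                             "biomass", "aboveground_hm", "root_hm"),
               score = c(0.87, 0.36, 0.34, 0, 1, 0.06, 0, 0.91, 0.98, 0.60)),
    data.frame(treatment = "RBC",
               indicator = c("pH", "SOM", "CEC", "A-N", "A-P", "A-K", "AHM",
                             "biomass", "aboveground_hm", "root_hm",
                             "amendment_hm", "stability"),
               score = c(0.89, 0.47, 0.34, 0.03, 1, 0.10, 0.33, 0.99, 1,
                         0.68, 1, 1)),
    data.frame(treatment = "HAP",
               indicator = c("pH", "SOM", "CEC", "A-N", "A-P", "A-K", "AHM",
                             "biomass", "aboveground_hm", "root_hm",
                             "amendment_hm", "stability"),
               score = c(0.95, 0.39, 0.21, 0, 1, 0.58, 0.63, 1, 1, 0.71,
                         1, 1))
  )
  long
}
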