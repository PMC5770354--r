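# Synthetic benchmark generators.
#
# Real descriptor+fingerprint tables are strongly collinear: descriptor
# families (size, lipophilicity, polarity, ...) move together, so compounds
# occupy a low-dimensional manifold inside the wide feature table. The
# generators emulate this with a Gaussian copula: a few latent "chemical"
# factors drive every feature, each feature keeps a uniform [0,1] marginal,
# and a fraction of columns is binarized to mimic fingerprint bits. The
# response depends on a known sparse subset of features, which gives every
# downstream stage (modelability, ranking recovery, selection benefit) a
# ground truth to be tested against.

#' Generate a synthetic QSAR regression benchmark
#'
#' Draws \code{n} compounds in a \code{p}-dimensional feature space with
#' uniform \[0, 1\] marginals and block-correlated structure
#' (\code{latent_dim} latent factors, within-block correlation
#' \code{latent_cor}), binarizes a fraction of columns into fingerprint-like
#' bits, and builds a response in \[0, 1\] from \code{n_informative} known
#' features plus Gaussian noise. The nonlinear response form adds an
#' interaction and a quadratic term to the weighted sum.
#'
#' @param n,p Number of compounds and features.
#' @param n_informative Number of features driving the response.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   \[0, 1\] response scale.
#' @param seed Integer seed; the output is a pure function of the
#'   arguments.
#' @param response_form \code{"nonlinear"} (default) or \code{"linear"}.
#' @param binary_fraction Fraction of columns binarized at 0.5 to mimic
#'   fingerprint bits (default 0.5).
#' @param latent_dim Number of latent factors (default 4).
#' @param latent_cor Range of the squared loading of background features on
#'   their latent factor (default \code{c(0.3, 0.9)}): descriptor tables mix
#'   tightly collinear families with weakly coupled features, so per-feature
#'   loadings are drawn uniformly from this range.
#' @param informative_cor Squared latent loading of the informative
#'   features (default 0.5): activity is driven by specific structural
#'   content, not only by the global-property factors every feature shares.
#' @return A list with \code{features} (a \code{feature_matrix}),
#'   \code{activity} (numeric in \[0, 1\]), and \code{informative}
#'   (character vector of ground-truth informative feature names).
#' @export
make_regression_dataset <- function(n = 300L, p = 200L, n_informative = 10L,
                                    noise_sd = 0.05, seed = 1L,
                                    response_form = c("nonlinear", "linear"),
                                    binary_fraction = 0.5,
                                    latent_dim = 4L,
                                    latent_cor = c(0.3, 0.9),
                                    informative_cor = 0.5) {
  response_form <- match.arg(response_form)
  if (n_informative > p || n < 2L || p < 1L || n_informative < 1L)
    config_error("invalid synthetic spec: need n >= 2, p >= 1, n_informative <= p")
  if (noise_sd < 0) config_error("noise_sd must be non-negative")
  if (binary_fraction < 0 || binary_fraction > 1)
    config_error("binary_fraction must lie in [0, 1]")

  with_seed(seed, {
    width <- max(3L, nchar(as.character(p)))
    feat_names <- sprintf("feat_%0*d", width, seq_len(p))
    n_bin <- floor(binary_fraction * p)
    bin_cols <- if (n_bin > 0) seq.int(p - n_bin + 1L, p) else integer(0)

    # Gaussian copula: feature j loads on one latent factor with loading
    # sqrt(latent_cor); pnorm gives exact uniform [0,1] marginals.
    factors <- matrix(stats::rnorm(n * latent_dim), n, latent_dim)
    assign_dim <- sample.int(latent_dim, p, replace = TRUE)
    load_sign <- sample(c(-1, 1), p, replace = TRUE)

    # informative features are drawn from the continuous (descriptor-like)
    # block when possible, with coherent positive loadings so their latent
    # parts do not cancel in the response
    cont_cols <- if (n_bin > 0) seq_len(p - n_bin) else seq_len(p)
    pool <- if (length(cont_cols) >= n_informative) cont_cols else seq_len(p)
    informative <- sort(sample(pool, n_informative))
    load_sign[informative] <- 1

    lam2 <- stats::runif(p, latent_cor[1L], latent_cor[2L])
    lam2[informative] <- informative_cor
    Z <- factors[, assign_dim, drop = FALSE] *
      rep(load_sign * sqrt(lam2), each = n) +
      matrix(stats::rnorm(n * p), n, p) * rep(sqrt(1 - lam2), each = n)
    X <- stats::pnorm(Z)
    if (n_bin > 0) X[, bin_cols] <- as.numeric(X[, bin_cols] > 0.5)
    dimnames(X) <- list(sprintf("cpd_%0*d", max(3L, nchar(as.character(n))),
                                seq_len(n)), feat_names)

    w <- stats::runif(n_informative, 0.5, 1.5)
    lin <- as.vector(X[, informative, drop = FALSE] %*% w)
    raw <- lin
    if (response_form == "nonlinear" && n_informative >= 3L) {
      raw <- raw + 1.5 * X[, informative[1L]] * X[, informative[2L]] +
        1.0 * X[, informative[3L]]^2
    }
    squashed <- if (max(raw) > min(raw))
      (raw - min(raw)) / (max(raw) - min(raw)) else rep(0.5, n)
    y <- squashed + stats::rnorm(n, sd = noise_sd)
    y <- pmin(pmax(y, 0), 1)

    kinds <- rep("descriptor", p)
    kinds[bin_cols] <- "fingerprint"
    list(features = feature_matrix(X, kinds),
         activity = stats::setNames(y, rownames(X)),
         informative = feat_names[informative])
  })
}

#' Generate an activity-cliff benchmark
#'
#' Builds a dataset dominated by activity cliffs: for the cliff fraction of
#' compounds, pairs of near-identical feature rows (perturbation far below
#' the typical inter-compound distance) are assigned activities near 0 and
#' near 1 respectively, so every compound's nearest neighbour disagrees
#' maximally with it. Such datasets are exactly the low-modelability cases
#' the MODI gate is designed to catch. Remaining rows follow
#' \code{\link{make_regression_dataset}}.
#'
#' @inheritParams make_regression_dataset
#' @param cliff_fraction Fraction of compounds arranged in cliff pairs, in
#'   (0, 1\]; 0 delegates to \code{\link{make_regression_dataset}}.
#' @param perturbation Standard deviation of the within-pair feature
#'   perturbation (default 0.005).
#' @return A list with \code{features} and \code{activity}.
#' @export
make_activity_cliff_dataset <- function(n = 100L, p = 200L,
                                        cliff_fraction = 1,
                                        n_informative = 10L,
                                        noise_sd = 0.05, seed = 1L,
                                        perturbation = 0.005) {
  if (cliff_fraction < 0 || cliff_fraction > 1)
    config_error("cliff_fraction must lie in [0, 1]")
  if (cliff_fraction == 0) {
    out <- make_regression_dataset(n = n, p = p, n_informative = n_informative,
                                   noise_sd = noise_sd, seed = seed)
    return(list(features = out$features, activity = out$activity))
  }
  base <- make_regression_dataset(n = n, p = p, n_informative = n_informative,
                                  noise_sd = noise_sd, seed = seed)
  X <- fm_values(base$features)
  y <- unname(base$activity)
  with_seed(seed + 7919L, {
    n_cliff_pairs <- floor(cliff_fraction * n / 2)
    if (n_cliff_pairs > 0) {
      for (m in seq_len(n_cliff_pairs)) {
        i <- 2L * m - 1L; j <- 2L * m
        X[j, ] <- pmin(pmax(
          X[i, ] + stats::rnorm(ncol(X), sd = perturbation), 0), 1)
        y[i] <- stats::runif(1, 0, 0.05)
        y[j] <- stats::runif(1, 0.95, 1)
      }
    }
    kinds <- rep("descriptor", ncol(X))  # perturbation breaks binarization
    list(features = feature_matrix(X, kinds),
         activity = stats::setNames(y, rownames(X)))
  })
}

#' Embedded SMILES fixture exercising every curation branch
#'
#' A hand-curated list of valid drug-like structures with plausible nM
#' activities, plus deliberately planted records: a salt form of a compound
#' already present as its parent, duplicate structures written as different
#' SMILES with distinct and with absent years, one invalid SMILES, one
#' record with a missing activity value, and records of a second activity
#' type. Intended for tests and demos of the curation stage; no file or
#' network access involved.
#'
#' @return A data.frame with columns \code{compound_id}, \code{smiles},
#'   \code{activity_type}, \code{activity_value}, \code{year}.
#' @export
make_smiles_fixture <- function() {
  rec <- function(id, smi, type, value, year)
    data.frame(compound_id = id, smiles = smi, activity_type = type,
               activity_value = value, year = year, stringsAsFactors = FALSE)
  rbind(
    # -- clean Ki records (unique structures) --
    rec("CPD001", "CC(=O)Oc1ccccc1C(=O)O", "Ki", 5200, 2012),          # aspirin
    rec("CPD002", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "Ki", 310, 2014),      # ibuprofen
    rec("CPD003", "CC(=O)Nc1ccc(O)cc1", "Ki", 8400, 2011),             # paracetamol
    rec("CPD004", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "Ki", 12000, 2013),    # caffeine
    rec("CPD005", "CN1CCC[C@H]1c1cccnc1", "Ki", 45, 2015),             # nicotine
    rec("CPD006", "NCCc1ccc(O)c(O)c1", "Ki", 980, 2010),               # dopamine
    rec("CPD007", "NCCc1c[nH]c2ccccc12", "Ki", 150, 2016),             # tryptamine
    rec("CPD008", "CNC[C@H](O)c1ccc(O)c(O)c1", "Ki", 62, 2017),        # epinephrine
    rec("CPD009", "OC(=O)c1ccccc1O", "Ki", 9100, 2009),                # salicylic acid
    rec("CPD010", "Clc1ccccc1-c1nc2ccccc2[nH]1", "Ki", 21, 2018),
    rec("CPD011", "COc1ccc2cc(ccc2c1)C(C)C(=O)O", "Ki", 77, 2013),     # naproxen
    rec("CPD012", "NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O", "Ki", 3400, 2012),
    rec("CPD013", "CC(N)Cc1ccccc1", "Ki", 5600, 2014),                 # amphetamine
    rec("CPD014", "OCCN1CCN(CC1)CCCN1c2ccccc2Sc2ccc(Cl)cc12", "Ki", 9, 2016),
    rec("CPD015", "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc12", "Ki", 14, 2015), # diazepam
    rec("CPD016", "Oc1ccc(CCN2CCCCC2)cc1", "Ki", 230, 2011),
    rec("CPD017", "COc1cc2c(cc1OC)C(=O)C(CC1CCN(CC1)Cc1ccccc1)C2", "Ki", 6, 2019), # donepezil
    rec("CPD018", "CN(C)CCCN1c2ccccc2CCc2ccccc12", "Ki", 38, 2014),    # imipramine
    rec("CPD019", "NC(=O)c1ccc(cc1)S(=O)(=O)N", "Ki", 7800, 2010),
    rec("CPD020", "CC(CS)C(=O)N1CCCC1C(=O)O", "Ki", 1900, 2013),       # captopril
    rec("CPD021", "Nc1ncnc2n(cnc12)[C@H]1O[C@@H](CO)[C@H](O)[C@@H]1O", "Ki", 4400, 2012), # adenosine
    rec("CPD022", "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1", "Ki", 520, 2015),  # atenolol
    rec("CPD023", "CC(C)NCC(O)COc1cccc2ccccc12", "Ki", 88, 2016),      # propranolol
    rec("CPD024", "OC(=O)CCCCCCC(=O)Nc1ccccc1", "Ki", 2600, 2011),
    rec("CPD025", "CCOC(=O)C1(CCN(C)CC1)c1ccccc1", "Ki", 410, 2013),
    rec("CPD026", "CSCC[C@H](N)C(=O)O", "Ki", 11000, 2009),            # methionine
    rec("CPD027", "OCC(O)CO", "Ki", 25000, 2008),                      # glycerol
    rec("CPD028", "c1ccc2c(c1)oc1ccccc12", "Ki", 670, 2017),           # dibenzofuran
    rec("CPD029", "CN1CCN(CC1)c1ccc(N)cc1", "Ki", 130, 2018),
    rec("CPD030", "CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O", "Ki", 2100, 2014), # penicillin G
    # -- planted duplicate pair with distinct years: keep the 2015 record --
    rec("CPD031", "Oc1ccccc1", "Ki", 6000, 2010),                      # phenol
    rec("CPD032", "c1ccccc1O", "Ki", 4000, 2015),                      # phenol again
    # -- planted duplicate trio, no years: keep the median-activity record --
    rec("CPD033", "Cc1ccccc1N", "Ki", 100, NA),                        # o-toluidine
    rec("CPD034", "Nc1ccccc1C", "Ki", 300, NA),
    rec("CPD035", "Cc1ccccc1N", "Ki", 900, NA),
    # -- planted salt form of CPD002 (ibuprofen sodium): desalts to parent --
    rec("CPD036", "CC(C)Cc1ccc(cc1)C(C)C(=O)[O-].[Na+]", "Ki", 450, 2012),
    # -- planted invalid SMILES --
    rec("CPD037", "notasmiles", "Ki", 100, 2015),
    # -- planted missing activity value --
    rec("CPD038", "CCN(CC)CC", "Ki", NA, 2014),                        # triethylamine
    # -- other activity type: dropped when Ki is requested --
    rec("CPD039", "CCOC(=O)c1ccccc1N", "IC50", 140, 2013),
    rec("CPD040", "COc1ccccc1OCCN", "IC50", 260, 2012),
    rec("CPD041", "CC(O)c1ccccc1", "IC50", 3100, 2011)
  )
}
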