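## synthetic_data: generators for peptide pools, anchor-motif binding,
## bimodal BA/EL training scores, biased predictors and proteomes.

## Swiss-Prot average amino-acid composition (percent), used as the
## proteome-like residue frequency preset.
.PROTEOME_FREQ_PCT <- c(
    A = 8.26, C = 1.37, D = 5.46, E = 6.74, F = 3.86,
    G = 7.08, H = 2.27, I = 5.94, K = 5.82, L = 9.66,
    M = 2.41, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
    S = 6.56, T = 5.34, V = 6.87, W = 1.09, Y = 2.92)

#' Residue frequency presets
#'
#' \code{"uniform"} assigns 1/20 to every canonical residue and is the
#' default for unit-scale simulations. \code{"proteome"} uses the
#' Swiss-Prot average amino-acid composition, for runs that should look
#' like fragments of real proteins.
#'
#' @param preset \code{"uniform"} or \code{"proteome"}.
#' @return Named numeric vector over the 20 canonical residues, summing
#'   to 1.
#'
#' @export
residueFreqs <- function(preset = c("uniform", "proteome")) {
    preset <- match.arg(preset)
    f <- switch(preset,
                uniform = stats::setNames(rep(1 / 20, 20), .AA_ALPHABET),
                proteome = .PROTEOME_FREQ_PCT[.AA_ALPHABET] /
                    sum(.PROTEOME_FREQ_PCT))
    f
}

.checkFreqs <- function(freqs) {
    if (!is.numeric(freqs) || length(freqs) != 20L ||
        !setequal(names(freqs), .AA_ALPHABET))
        stop("'freqs' must be a numeric vector named by the 20 canonical ",
             "residues")
    if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8)
        stop("'freqs' must be non-negative and sum to 1")
    freqs[.AA_ALPHABET]
}

#' Generate background peptides
#'
#' Draws \code{n} i.i.d. peptides of the given length, residue by
#' residue from the supplied frequency vector. Reproducible under a
#' fixed seed.
#'
#' @param n Number of peptides (0 allowed).
#' @param length Peptide length; default 9.
#' @param freqs Residue frequencies (see [residueFreqs()]); default
#'   uniform.
#' @param seed Optional integer seed.
#' @return Character vector of peptides.
#'
#' @export
genBackgroundPeptides <- function(n, length = 9,
                                  freqs = residueFreqs("uniform"),
                                  seed = NULL) {
    stopifnot(is.numeric(n), n >= 0, is.numeric(length), length >= 1)
    freqs <- .checkFreqs(freqs)
    n <- as.integer(n)
    length <- as.integer(length)
    if (n == 0L)
        return(character(0))
    .withSeed(seed, {
        m <- matrix(sample(.AA_ALPHABET, n * length, replace = TRUE,
                           prob = freqs),
                    nrow = n, ncol = length)
        do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    })
}

#' Construct a motif model
#'
#' @param allele Allele label.
#' @param anchors Named list mapping 1-based positions to character
#'   vectors of favoured residues, e.g. \code{list(`2` = c("L","V"))}.
#' @param reward Reward per matched anchor (length 1 or one per
#'   anchor).
#' @param penalty Penalty per mismatched anchor (non-negative).
#' @param baseline Baseline raw score before the logistic.
#' @param steepness Logistic steepness (> 0).
#' @return A [MotifModel-class] object.
#'
#' @seealso [motifPreset()] for the shipped allele presets.
#' @export
MotifModel <- function(allele, anchors, reward = 1, penalty = 1,
                       baseline = -1, steepness = 1.5) {
    new("MotifModel", allele = allele, anchors = anchors,
        reward = as.numeric(reward), penalty = as.numeric(penalty),
        baseline = as.numeric(baseline), steepness = as.numeric(steepness))
}

#' Shipped allele motif presets
#'
#' Stylised anchor preferences of three well-characterised HLA class I
#' supertype alleles:
#' \itemize{
#'   \item \code{"A2"} (HLA-A*02:01): hydrophobic L/V/M/I at positions
#'     2 and 9 — prefers hydrophobic peptides.
#'   \item \code{"B27"} (HLA-B*27:05): hydrophilic arginine at position
#'     2 — prefers slightly hydrophilic peptides.
#'   \item \code{"B8"} (HLA-B*08:01): L/V/M/I at positions 2 and 9 plus
#'     hydrophilic R/K at positions 3 and 5 — balanced preference.
#' }
#' Rewards, penalties, baseline and steepness are chosen so that under a
#' uniform background roughly the top few percent of 9-mers are strong
#' binders and the latent score classes overlap moderately once
#' predictor noise is added (realistic, imperfect separability).
#'
#' @param allele One of \code{"A2"}, \code{"B27"}, \code{"B8"}.
#' @return A [MotifModel-class] object.
#'
#' @export
motifPreset <- function(allele = c("A2", "B27", "B8")) {
    allele <- match.arg(allele)
    hydroph <- c("L", "V", "M", "I")
    switch(allele,
           A2 = MotifModel("HLA-A*02:01",
                           anchors = list(`2` = hydroph, `9` = hydroph),
                           reward = 1, penalty = 1,
                           baseline = -1, steepness = 1.5),
           B27 = MotifModel("HLA-B*27:05",
                            anchors = list(`2` = "R"),
                            reward = 2, penalty = 2,
                            baseline = -1, steepness = 1.5),
           B8 = MotifModel("HLA-B*08:01",
                           anchors = list(`2` = hydroph, `9` = hydroph,
                                          `3` = c("R", "K"),
                                          `5` = c("R", "K")),
                           reward = 0.75, penalty = 0.75,
                           baseline = -1.25, steepness = 1.5))
}

#' Latent true binding score under a motif model
#'
#' Deterministic logistic score: each anchor position contributes its
#' reward when the peptide carries a favoured residue there and minus
#' its penalty otherwise; the raw sum (plus baseline) is passed through
#' a logistic with the model's steepness, so the score is strictly
#' inside (0, 1) and increases with the number of matched anchors.
#'
#' @param motif A [MotifModel-class] object.
#' @param peptides Character vector of peptides, each long enough to
#'   cover every anchor position.
#' @return Numeric vector of latent binding scores in (0, 1).
#'
#' @examples
#' m <- motifPreset("B27")
#' trueBindingScore(m, "ARAAAAAAA") > trueBindingScore(m, "AAAAAAAAA")
#' @export
trueBindingScore <- function(motif, peptides) {
    stopifnot(is(motif, "MotifModel"))
    peptides <- validatePeptides(peptides)
    pos <- as.integer(names(motif@anchors))
    if (any(nchar(peptides) < max(pos)))
        stop("peptide shorter than the motif's largest anchor position (",
             max(pos), ")")
    k <- length(motif@anchors)
    reward <- rep_len(motif@reward, k)
    penalty <- rep_len(motif@penalty, k)
    raw <- rep(motif@baseline, length(peptides))
    for (i in seq_len(k)) {
        hit <- substr(peptides, pos[i], pos[i]) %in% motif@anchors[[i]]
        raw <- raw + ifelse(hit, reward[i], -penalty[i])
    }
    stats::plogis(motif@steepness * raw)
}

#' Construct a biased synthetic predictor
#'
#' @param label Predictor label for reports.
#' @param noiseSd Standard deviation of logit-scale Gaussian noise
#'   (>= 0).
#' @param beta Hydrophobicity bias per hydrophobicity unit on the logit
#'   scale; 0 gives the unbiased predictor.
#' @return A [BiasedPredictor-class] object.
#'
#' @export
BiasedPredictor <- function(label = "synthetic", noiseSd = 0.5, beta = 0) {
    new("BiasedPredictor", label = label, noiseSd = as.numeric(noiseSd),
        beta = as.numeric(beta))
}

#' Generate predictor scores with injected hydrophobicity bias
#'
#' Implements the bias-injection model on the logit scale:
#' \deqn{logit(pred) = logit(true) + beta * H(peptide) + noise}
#' with Gaussian noise of standard deviation \code{noiseSd} and
#' \code{H} the total hydrophobicity under \code{scale}. True scores
#' are clamped into \code{[eps, 1 - eps]} before the logit so it stays
#' finite; with \code{beta = 0} and \code{noiseSd = 0} the predicted
#' scores equal the true scores up to that clamping tolerance.
#'
#' @param peptides Character vector of peptides.
#' @param trueScores Latent true binding scores in (0, 1), one per
#'   peptide.
#' @param predictor A [BiasedPredictor-class] object.
#' @param scale A [HydrophobicityScale-class]; default Moon.
#' @param seed Optional integer seed for the noise.
#' @param eps Clamping tolerance before the logit; default 1e-6.
#' @return Numeric vector of predicted scores in (0, 1).
#'
#' @export
genPredictorScores <- function(peptides, trueScores, predictor,
                               scale = hydroScale("moon"), seed = NULL,
                               eps = 1e-6) {
    stopifnot(is(predictor, "BiasedPredictor"),
              length(peptides) == length(trueScores))
    h <- peptideHydrophobicity(peptides, scale)
    lt <- stats::qlogis(.clampUnit(trueScores, eps))
    noise <- if (predictor@noiseSd > 0)
        .withSeed(seed, stats::rnorm(length(lt), 0, predictor@noiseSd))
    else rep(0, length(lt))
    stats::plogis(lt + predictor@beta * h + noise)
}

#' Assemble a PredictorRun from synthetic scores
#'
#' Attaches the predictor's own strong-binder calls by flagging its top
#' \code{flagFraction} of predicted scores (ties at the cutoff score
#' are flagged too), emulating the percentage-rank calls external tools
#' report alongside their scores.
#'
#' @param peptides Character vector of peptides.
#' @param predictedScores Predicted scores in [0, 1].
#' @param flagFraction Fraction of records the predictor flags as
#'   strong binders; default 0.05.
#' @param measuredScores Optional measured scores (training mode).
#' @param assay Optional assay tags.
#' @param tool,allele Run labels.
#' @return A [PredictorRun-class] object.
#'
#' @export
makePredictorRun <- function(peptides, predictedScores,
                             flagFraction = 0.05,
                             measuredScores = NA_real_,
                             assay = NA_character_,
                             tool = "synthetic", allele = "allele") {
    stopifnot(flagFraction > 0, flagFraction <= 1)
    n <- length(predictedScores)
    nflag <- max(1L, ceiling(flagFraction * n))
    cutoff <- sort(predictedScores, decreasing = TRUE)[nflag]
    PredictorRun(peptide = peptides, predicted_score = predictedScores,
                 strong_binder = predictedScores >= cutoff,
                 measured_score = measuredScores, assay = assay,
                 tool = tool, allele = allele)
}

#' Construct a training-set specification
#'
#' Defaults reflect the structure of real class I training data: mostly
#' binary eluted-ligand records with a minority of continuous
#' binding-affinity records, such that 15 percent of all measured
#' scores fall strictly inside (0, 1).
#'
#' @param n Number of records; default 50000.
#' @param binderFraction Target true-binder fraction; default 0.05.
#' @param nonExtremeFraction Fraction of records with a measured score
#'   strictly inside (0, 1); default 0.15.
#' @param baFraction Fraction of BA-assay records; default 0.2. Must be
#'   at least \code{nonExtremeFraction}, since only BA scores are
#'   continuous.
#' @return A [TrainingSetSpec-class] object.
#'
#' @export
TrainingSetSpec <- function(n = 50000, binderFraction = 0.05,
                            nonExtremeFraction = 0.15, baFraction = 0.2) {
    new("TrainingSetSpec", n = as.integer(n),
        binderFraction = as.numeric(binderFraction),
        nonExtremeFraction = as.numeric(nonExtremeFraction),
        baFraction = as.numeric(baFraction))
}

## EL binarisation threshold: the smallest distinct true-score value
## whose at-or-above rate does not exceed the binder fraction (falling
## back to the largest value when even the top class is more frequent).
## With discrete motif scores the achieved rate is the closest
## achievable rate not exceeding the target.
.elThreshold <- function(trueScores, binderFraction) {
    vals <- sort(unique(trueScores), decreasing = TRUE)
    rates <- vapply(vals, function(v) mean(trueScores >= v), numeric(1))
    ok <- which(rates <= binderFraction)
    if (length(ok) == 0L)
        return(vals[1L])
    vals[max(ok)]
}

#' Generate a synthetic training set
#'
#' Emulates the bimodal structure of class I training data. Peptides
#' are drawn from the background frequencies and scored by the motif
#' model; a binarisation threshold on the latent true score is set so
#' the positive rate matches the spec's binder fraction as closely as
#' the discrete motif scores allow. Records are assigned BA or EL assay
#' tags at the spec's BA fraction. EL records — and BA records outside
#' the non-extreme quota — get a binary measured score (1 for true
#' binders, 0 otherwise). The configured fraction of all records
#' (necessarily BA) instead get a continuous measured score strictly
#' inside (0, 1): the true score jittered on the logit scale with
#' standard deviation \code{baNoiseSd}, representing assay noise.
#'
#' @param spec A [TrainingSetSpec-class] object.
#' @param motif A [MotifModel-class] object; default the A2 preset.
#' @param freqs Background residue frequencies; default uniform.
#' @param seed Optional integer seed.
#' @param baNoiseSd Logit-scale SD of BA assay noise; default 1.
#' @param scale A [HydrophobicityScale-class] (unused by generation but
#'   recorded for provenance); default Moon.
#' @return \code{data.frame} with columns \code{peptide},
#'   \code{true_score} (latent, not part of any file format),
#'   \code{measured_score} and \code{assay}.
#'
#' @export
genTrainingSet <- function(spec = TrainingSetSpec(),
                           motif = motifPreset("A2"),
                           freqs = residueFreqs("uniform"),
                           seed = NULL, baNoiseSd = 1,
                           scale = hydroScale("moon")) {
    stopifnot(is(spec, "TrainingSetSpec"), is(motif, "MotifModel"))
    n <- spec@n
    peptides <- genBackgroundPeptides(n, 9, freqs, .childSeed(seed, 1L))
    true <- trueBindingScore(motif, peptides)
    thr <- .elThreshold(true, spec@binderFraction)
    binder <- true >= thr
    .withSeed(.childSeed(seed, 2L), {
        isBA <- stats::runif(n) < spec@baFraction
        ## non-extreme records live inside the BA subset
        pNonExtremeGivenBA <- if (spec@baFraction > 0)
            spec@nonExtremeFraction / spec@baFraction else 0
        nonExtreme <- isBA & (stats::runif(n) < pNonExtremeGivenBA)
        measured <- as.numeric(binder)
        if (any(nonExtreme)) {
            lt <- stats::qlogis(.clampUnit(true[nonExtreme]))
            m <- stats::plogis(lt + stats::rnorm(sum(nonExtreme), 0,
                                                 baNoiseSd))
            measured[nonExtreme] <- .clampUnit(m)
        }
        data.frame(peptide = peptides,
                   true_score = true,
                   measured_score = measured,
                   assay = ifelse(isBA, "BA", "EL"),
                   stringsAsFactors = FALSE)
    })
}

#' Generate a biased/unbiased predictor pair on one training set
#'
#' The core simulation behind the audit's bias-recovery property: one
#' peptide pool with motif-driven true binding and training-style
#' measured scores, scored by two synthetic predictors that differ only
#' in their hydrophobicity bias coefficient. Both runs share peptides
#' and measured scores, so differences in their audits are attributable
#' to the injected bias alone.
#'
#' @param n Number of peptides; default 20000.
#' @param motif A [MotifModel-class]; default the A2 preset.
#' @param beta Bias coefficient of the biased predictor; default 0.4.
#' @param noiseSd Logit-scale noise SD of both predictors; default 0.5.
#' @param flagFraction Fraction each predictor flags as strong binders;
#'   default 0.05.
#' @param freqs Background residue frequencies; default uniform.
#' @param seed Optional integer seed.
#' @param scale A [HydrophobicityScale-class]; default Moon.
#' @return List with elements \code{training} (the
#'   [genTrainingSet()] data.frame), \code{unbiased} and \code{biased}
#'   (two [PredictorRun-class] objects).
#'
#' @export
genBiasedPair <- function(n = 20000, motif = motifPreset("A2"),
                          beta = 0.4, noiseSd = 0.5,
                          flagFraction = 0.05,
                          freqs = residueFreqs("uniform"),
                          seed = NULL, scale = hydroScale("moon")) {
    spec <- TrainingSetSpec(n = n)
    ts <- genTrainingSet(spec, motif, freqs, seed = .childSeed(seed, 10L),
                         scale = scale)
    mk <- function(label, b, k) {
        pred <- genPredictorScores(
            ts$peptide, ts$true_score,
            BiasedPredictor(label, noiseSd = noiseSd, beta = b),
            scale = scale, seed = .childSeed(seed, k))
        makePredictorRun(ts$peptide, pred, flagFraction = flagFraction,
                         measuredScores = ts$measured_score,
                         assay = ts$assay, tool = label,
                         allele = motif@allele)
    }
    list(training = ts,
         unbiased = mk("unbiased", 0, 11L),
         biased = mk("biased", beta, 12L))
}

#' Generate a synthetic proteome
#'
#' Random protein sequences with i.i.d. residues, for exercising the
#' proteome-audit path. Protein lengths are drawn from a rounded normal
#' distribution (degenerate at \code{meanLength} when
#' \code{sdLength = 0}, the default) and truncated below at
#' \code{minLength}.
#'
#' @param nProteins Number of proteins; default 100.
#' @param meanLength Mean protein length; default 517.
#' @param sdLength SD of protein length; default 0 (fixed length).
#' @param minLength Minimum protein length; default 9.
#' @param freqs Residue frequencies; default the proteome-like preset.
#' @param seed Optional integer seed.
#' @return An \code{AAStringSet} with names \code{synprot_0001, ...};
#'   the \code{synthetic_} prefix in written FASTA headers marks these
#'   as simulated stand-ins, not real proteins.
#'
#' @export
genSyntheticProteome <- function(nProteins = 100, meanLength = 517,
                                 sdLength = 0, minLength = 9,
                                 freqs = residueFreqs("proteome"),
                                 seed = NULL) {
    stopifnot(nProteins >= 1, sdLength >= 0)
    if (meanLength < minLength)
        stop("meanLength (", meanLength, ") must be at least minLength (",
             minLength, ")")
    freqs <- .checkFreqs(freqs)
    .withSeed(seed, {
        lens <- if (sdLength == 0) rep(as.integer(meanLength), nProteins)
                else pmax(as.integer(minLength),
                          as.integer(round(stats::rnorm(nProteins,
                                                        meanLength,
                                                        sdLength))))
        seqs <- vapply(lens, function(L)
            paste(sample(.AA_ALPHABET, L, replace = TRUE, prob = freqs),
                  collapse = ""), character(1))
        out <- Biostrings::AAStringSet(seqs)
        names(out) <- sprintf("synthetic_prot_%04d", seq_len(nProteins))
        out
    })
}

#' Recover the injected bias coefficient
#'
#' Least-squares regression of the logit-scale residual
#' \code{logit(pred) - logit(true)} on total hydrophobicity. Under the
#' bias-injection model the slope estimates \code{beta}; applied to an
#' external predictor's scores against a reference, it quantifies the
#' predictor's hydrophobicity bias per hydrophobicity unit.
#'
#' @inheritParams genPredictorScores
#' @param predictedScores Predicted scores in (0, 1).
#' @return List with \code{beta_hat} (slope), \code{intercept} and
#'   \code{se} (slope standard error).
#'
#' @export
estimateBias <- function(peptides, trueScores, predictedScores,
                         scale = hydroScale("moon"), eps = 1e-6) {
    h <- peptideHydrophobicity(peptides, scale)
    resid <- stats::qlogis(.clampUnit(predictedScores, eps)) -
        stats::qlogis(.clampUnit(trueScores, eps))
    fit <- stats::lm(resid ~ h)
    co <- summary(fit)$coefficients
    list(beta_hat = unname(co["h", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         se = unname(co["h", "Std. Error"]))
}
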