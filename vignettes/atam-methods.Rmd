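---
title: "The ailment topic aspect model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ailment topic aspect model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atam)
```

## The problem

Short self-reported health messages (tweets and similar) mix three kinds of
words: words about an *ailment* (flu, fever, eye drops), words about an
ordinary *topic* the message also touches (home, watching, tv), and
*background* words that carry no topical content (damn, with, a). A plain
topic model blurs these together: symptom terms form their own clusters,
ailment clusters absorb noise, and the resulting groups are hard to read off
as illnesses. The ailment topic aspect model (ATAM) implemented here
separates the three roles explicitly so that each document receives one
latent ailment label and each token is explained by the part of the model it
actually belongs to. Document-level ailment assignments can then be
aggregated into prevalence series over time or regions and compared against
surveillance data.

## The model

Each document $d$ draws an ailment $a_d = i$ with probability $\eta_i$,
topic proportions $\theta_d \sim \mathrm{Dir}(\alpha_i)$ (note the prior
depends on the ailment, which lets ailments associate with particular
topics), and an ailment-word proportion $\pi_d \sim
\mathrm{Beta}(\gamma, \gamma)$. Every token carries an *observed* aspect
label $y_{dn} \in \{\text{general}, \text{symptom}, \text{treatment}\}$,
assigned before inference by greedy keyphrase matching against a
symptom/treatment lexicon. Token $n$ of document $d$ is then generated as:

* with probability $1 - \lambda$ it is **background**: the word comes from
  a corpus-wide background distribution $\phi_{B,y_{dn}}$ (one per aspect);
* otherwise, with probability $\pi_d$ it is an **ailment word**: the word
  comes from $\phi_{A, a_d, y_{dn}}$ — each ailment owns three word
  distributions, one per aspect;
* otherwise it is a **topic word**: a topic $z_{dn} = k$ is drawn from
  $\theta_d$ and the word from $\phi_{T,k}$, exactly as in LDA.

Priors: $\eta \sim \mathrm{Dir}(\sigma)$; topic and background word
distributions get symmetric $\mathrm{Dir}(\beta)$; each ailment's word
distributions share an informative prior $\mathrm{Dir}(s_i m_i)$, where the
mean $m_i$ is the (smoothed) empirical unigram distribution of reference
articles about ailment $i$ and the precision $s_i$ says how strongly to
trust it. $\lambda$ is fixed, not inferred: it is the operator's control on
noise filtering.

The package also implements the comparison baseline `lda_bg()`: standard
LDA plus one shared background distribution under the same $\lambda$
switch.

## Inference

All multinomial parameters are integrated out and a collapsed Gibbs sampler
alternates between:

* **document ailments** $a_d$: proportional to the prevalence factor
  $(n^{-d}_i + \sigma)$, the Dirichlet-multinomial predictive of *all* of
  the document's ailment-state tokens (grouped by aspect, accumulated by
  the chain rule with log-gamma arithmetic, since they move jointly), and
  the Dirichlet-multinomial predictive of the document's topic counts under
  $\alpha_i$. The last factor exists because $\theta_d$'s prior depends on
  $a_d$. This product is accumulated in log space and normalized by
  log-sum-exp.
* **token states**: a single block draw over the $Z + 2$ composite
  outcomes (background; ailment; each topic). Blocking the three switch
  variables into one draw targets the same conditional as drawing them in
  sequence but removes any ordering ambiguity. The factors are bounded
  ratios, so this draw is safe in linear space.

The printed forms of these conditionals never survive into the code as
trusted truth: the test suite enumerates every latent configuration of tiny
instances, computes the exact collapsed posterior with an independent plain-R
implementation of the joint, and requires (a) the conditionals to match the
renormalized exact joints to $10^{-10}$ and (b) the chain's empirical
configuration frequencies over 200,000 post-burn-in sweeps to match the
exact posterior within total variation 0.02.

Degenerate settings are defined, not special-cased away: $\lambda = 0$
forces every token to background; $\lambda = 1$ in `lda_bg` is standard
LDA; masking the ailment branch (`mask_ailment = TRUE`) forces
$\pi_d = 0$, which also removes the Beta factor from the topic branch —
the split variable is never drawn — and collapses ATAM's token conditional
onto the `lda_bg` conditional entrywise.

## Hyperparameter optimization

Every 10 sweeps (configurable) the Dirichlet hyperparameters are updated by
fixed-point iteration on the marginal likelihood of the sampled counts,
five passes per event: each $\alpha_i$ is free (its group is the topic-count
vectors of documents currently assigned ailment $i$), while the word-prior
means $m_i$ stay fixed and only the precisions $s_i$ move (their group is
the three aspect count vectors of ailment $i$). Both updates derive from a
lower bound, so a pass cannot decrease the group likelihood; the tests
verify the joint log likelihood across optimization events and check the
fixed points against dense grid searches. Guard rails chosen for stability
(the source material does not pin them down): a positive floor of $10^{-6}$
on every parameter, and ailment groups smaller than 5 documents keep their
previous $\alpha_i$. LDA's single $\alpha$ is kept exactly symmetric by
optimizing only its total mass with the fixed-mean update against a uniform
mean.

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `A`, `Z` | 20, 20 | number of ailments / non-ailment topics |
| `lambda` | 0.2 | probability a token is *not* background noise |
| `gamma` | 1.0 | symmetric Beta on each document's ailment-vs-topic split |
| `sigma` | 1.0 | symmetric Dirichlet on ailment prevalence |
| `beta` | 0.01 | symmetric Dirichlet on topic/background words |
| `s_init` | 100 | initial word-prior precision (then optimized) |
| `smoothing` | 0.01 | pseudo-count per word when building prior means |
| `iterations` | 8000 | Gibbs sweeps for a production fit |
| `hyper_every` / `hyper_passes` | 10 / 5 | optimization cadence |

The prior-mean smoothing deserves a word: the raw empirical distribution of
reference articles gives zero mass to words they never use, which would
forbid those words from ever being ailment words. A pseudo-count of 0.01
per vocabulary word keeps full support while leaving the reference signal
dominant.

## Large corpora

Two devices make big fits practical. First, an incremental schedule
(`make_schedule()`) feeds data in fractions $t = 0.1, \ldots, 1.0$ with
sweep counts proportional to $1/t$ — more sweeps on less data. Each level
gets at least one sweep and the remainder is distributed by a
highest-quotient rule, which makes the counts provably non-increasing in
$t$ and exactly exhaustive. Newly activated documents are initialized
greedily at the argmax of the current conditionals (ailment by prevalence,
token states left to right, then a final ailment pass); a sampling
initializer is available behind `extend_mode = "sample"`. Second,
`pooled_sweep()` implements approximate distributed sampling: document
shards sweep against a stale snapshot of the global word-count tables and
the global tables are rebuilt exactly from the pooled latent state
afterwards. With one shard this is bit-identical to the exact sweep (a
tested invariant), so the approximation is strictly opt-in.

Checkpoints are single JSON files carrying counts, assignments,
hyperparameters, schedule position and the RNG state; resuming reproduces
the uninterrupted trajectory bit-exactly.

## The simulator and what passing tests mean

`simulate_corpus()` draws corpora from the generative story itself at known
parameters, so inference is testable without any external data.
`separated_params()` builds the standard study conditions: every
ailment-aspect, topic and background distribution puts 95% of its mass
uniformly on its own disjoint block of the vocabulary (full support is kept
via the remaining 5%), per-ailment aspect probabilities 0.7/0.2/0.1 for
general/symptom/treatment, and $\alpha_i$ favouring topic $i$ so ailments
couple to topics as the model intends. A lexicon-mediated mode conditions
word draws on disjoint per-aspect vocabulary pools and returns the matching
toy lexicon, so the full corpus pipeline (tokenize, match, label)
reproduces the generated aspect labels exactly.

The standard recovery study (3 ailments, 3 topics, vocabulary 200, 2,000
documents of 15 tokens, informative priors at precision 200, 2,000 sweeps)
recovers document ailments at about 0.85 accuracy with prevalence mean
absolute error around 0.01–0.03. Word-distribution recovery is limited by
the study's own information content: with $\lambda = 0.2$ and the 0.1
treatment-aspect share, each (ailment, treatment) table receives only about
100 tokens, so even scoring against the *true* assignments the
posterior-mean estimator cannot get below roughly 0.27–0.30 mean L1 across
the nine matched rows; the fitted model lands near 0.33–0.35. For recovery
scoring the package therefore offers posterior-averaged estimates
(`average_estimates = TRUE`: a running mean of posterior-mean estimates
over the second half of the run), which removes single-sample assignment
noise; final-state estimates remain the default everywhere else.

The simulator emulates the generative story, timestamps/regions with
planted intensities, and lexicon-derived aspects. It deliberately does not
emulate real social-media features — orthographic noise, duplicate and
near-duplicate messages, relevance-classifier errors, bursty user behaviour
— so passing recovery tests demonstrates correctness of the inference
machinery, not robustness to those artefacts.

## Trends

`ailment_rate()` turns final-sample document assignments into per-bin
rates: the fraction of a bin's documents assigned to an ailment, with
documents lacking metadata excluded from both numerator and denominator
(rates over all ailments therefore sum to 1 in every bin). Weeks start on
Sunday, matching surveillance-week conventions; months key on
`YYYY-MM`; regions use their codes verbatim. `keyword_rate()` is the
keyword baseline (document presence, not multiplicity), `zscore()`
standardizes series for joint plotting, `pearson_r()` correlates aligned
series, and `compare_correlations()` implements the standard (approximate)
z-test for dependent correlations. On a synthetic corpus with a planted
sinusoidal ailment intensity (20 weekly bins, 5,000 documents per bin) the
inferred ailment's weekly rate series correlates with the planted intensity
at $r > 0.99$.

Using the final Gibbs sample for document assignments matches the intended
single-assignment usage; a posterior-mode alternative can be had by
tallying assignments across additional sweeps with `gibbs_sweep()`.

## Numerical policy and edge cases

Ailment conditionals are computed entirely in log space (many factors;
log-sum-exp normalization); token conditionals in linear space (four
bounded factors; no underflow is possible at realistic counts).
Non-finite conditionals or likelihoods raise errors naming the offending
factor rather than propagating. Tie-breaks are deterministic: greedy
argmax initialization takes the lowest index, as does the LDA topic
assignment rule. Empty documents, empty shards, zero-count optimization
groups and an empty active set are all defined no-ops, and the audit
(`audit_state()`) recounts every table from the latent state in plain R —
independently of the incremental C++ bookkeeping — after any operation the
tests exercise.

Study sizes used by the test suite and the acceptance script (tiny
enumerable instances; the 2,000-document recovery study; the 100,000
document trend study at 120 sweeps) were chosen so each check carries
enough data to be informative about its property while the whole battery
stays convenient to run routinely.

## Known limitations

* Aspect labels are observed input; mislabeled keyphrases propagate into
  the ailment word tables untouched.
* The number of ailments and topics is fixed, not inferred.
* Sharded pooling is the standard approximate scheme — within a sweep,
  shards do not see each other's updates — and is therefore not exactly
  the single-chain posterior; use one shard when exactness matters.
* Correlation p-values for short series (the realistic surveillance case)
  rest on a normal approximation; treat them as indicative.
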