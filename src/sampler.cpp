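// Collapsed Gibbs sampler cores for the ailment topic aspect model (ATAM)
// and the LDA-with-background baseline.
//
// Composite token-state codes (0-based, as exchanged with R minus one):
//   ATAM:   0 = background, 1 = ailment, 2+k = topic k   (k in [0, Z))
//   LDA-bg: 0 = background, 1+k = topic k
// A document ailment of -1 (or token state -1) marks a document that has not
// yet been brought into the sampler (the incremental data schedule).
//
// Count-table layouts are column-major so they can be handed back to R with a
// dim attribute and no copying gymnastics:
//   n_doc_topic[d + D*k], n_topic_word[k + Z*v],
//   n_ail_aspect_word[i + A*(j + Y*v)], n_bg_aspect_word[j + Y*v].

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double lg(double x) { return R::lgammafn(x); }

static int sample_linear(const std::vector<double>& p, const char* where) {
  double tot = 0.0;
  for (double x : p) {
    if (!R_finite(x) || x < 0.0) stop("non-finite probability in %s", where);
    tot += x;
  }
  if (tot <= 0.0) stop("zero total probability in %s", where);
  double u = unif_rand() * tot, c = 0.0;
  for (size_t q = 0; q < p.size(); q++) {
    c += p[q];
    if (u <= c) return (int)q;
  }
  return (int)p.size() - 1;
}

static int sample_from_log(std::vector<double>& lp, const char* where) {
  double mx = R_NegInf;
  for (double x : lp) {
    if (ISNAN(x) || x == R_PosInf) stop("non-finite log-probability in %s", where);
    if (x > mx) mx = x;
  }
  if (mx == R_NegInf) stop("all log-probabilities -Inf in %s", where);
  for (size_t q = 0; q < lp.size(); q++) lp[q] = std::exp(lp[q] - mx);
  return sample_linear(lp, where);
}

static int argmax_vec(const std::vector<double>& p) {
  int best = 0;
  for (size_t q = 1; q < p.size(); q++) if (p[q] > p[best]) best = (int)q;
  return best;
}

// ---------------------------------------------------------------- ATAM core

struct ATAM {
  int A, Z, W, Y, D, T;
  double lambda, gam, sigma, beta;
  NumericMatrix alpha;  // A x Z
  NumericMatrix m;      // A x W prior means
  NumericVector s;      // A precisions
  std::vector<double> alpha_sum;
  IntegerVector doc_ptr, word, aspect;  // flattened corpus (0-based)
  IntegerVector a, ts;                  // latent state (working copies)
  std::vector<int> n_ail, n_doc_topic, n_doc_ail, n_doc_top;
  std::vector<int> n_tw, n_tw_sum, n_aaw, n_aaw_sum, n_bgw, n_bgw_sum;
  int n_active;

  void init(List corpus, IntegerVector a_, IntegerVector ts_, List priors,
            Nullable<List> stats_) {
    doc_ptr = corpus["doc_ptr"];
    word = corpus["word"];
    aspect = corpus["aspect"];
    D = doc_ptr.size() - 1;
    T = word.size();
    A = as<int>(priors["A"]);
    Z = as<int>(priors["Z"]);
    W = as<int>(priors["W"]);
    Y = as<int>(priors["Y"]);
    lambda = as<double>(priors["lambda"]);
    gam = as<double>(priors["gamma"]);
    sigma = as<double>(priors["sigma"]);
    beta = as<double>(priors["beta"]);
    alpha = as<NumericMatrix>(priors["alpha"]);
    m = as<NumericMatrix>(priors["m"]);
    s = as<NumericVector>(priors["s"]);
    if (alpha.nrow() != A || alpha.ncol() != Z) stop("alpha must be A x Z");
    if (m.nrow() != A || m.ncol() != W) stop("prior mean matrix must be A x W");
    if (s.size() != A) stop("precision vector must have length A");
    alpha_sum.assign(A, 0.0);
    for (int i = 0; i < A; i++) {
      double t = 0.0;
      for (int k = 0; k < Z; k++) t += alpha(i, k);
      alpha_sum[i] = t;
    }
    a = clone(a_);
    ts = clone(ts_);
    if (stats_.isNotNull()) load_stats(as<List>(stats_)); else recount();
  }

  void alloc() {
    n_ail.assign(A, 0);
    n_doc_topic.assign((size_t)D * Z, 0);
    n_doc_ail.assign(D, 0);
    n_doc_top.assign(D, 0);
    n_tw.assign((size_t)Z * W, 0);
    n_tw_sum.assign(Z, 0);
    n_aaw.assign((size_t)A * Y * W, 0);
    n_aaw_sum.assign((size_t)A * Y, 0);
    n_bgw.assign((size_t)Y * W, 0);
    n_bgw_sum.assign(Y, 0);
  }

  void attach_token(int d, int t, int st) {
    ts[t] = st;
    int v = word[t], j = aspect[t];
    if (st == 0) {
      n_bgw[j + Y * v]++; n_bgw_sum[j]++;
    } else if (st == 1) {
      int i = a[d];
      n_aaw[i + A * (j + Y * v)]++; n_aaw_sum[i + A * j]++; n_doc_ail[d]++;
    } else {
      int k = st - 2;
      n_tw[k + Z * v]++; n_tw_sum[k]++;
      n_doc_topic[d + (size_t)D * k]++; n_doc_top[d]++;
    }
  }

  void detach_token(int d, int t) {
    int st = ts[t], v = word[t], j = aspect[t];
    if (st == 0) {
      n_bgw[j + Y * v]--; n_bgw_sum[j]--;
    } else if (st == 1) {
      int i = a[d];
      n_aaw[i + A * (j + Y * v)]--; n_aaw_sum[i + A * j]--; n_doc_ail[d]--;
    } else {
      int k = st - 2;
      n_tw[k + Z * v]--; n_tw_sum[k]--;
      n_doc_topic[d + (size_t)D * k]--; n_doc_top[d]--;
    }
    ts[t] = -1;
  }

  void detach_ail(int d) {
    int i = a[d];
    n_ail[i]--;
    for (int t = doc_ptr[d]; t < doc_ptr[d + 1]; t++)
      if (ts[t] == 1) {
        int j = aspect[t], v = word[t];
        n_aaw[i + A * (j + Y * v)]--; n_aaw_sum[i + A * j]--;
      }
    a[d] = -1;
  }

  void attach_ail(int d, int i) {
    a[d] = i;
    n_ail[i]++;
    for (int t = doc_ptr[d]; t < doc_ptr[d + 1]; t++)
      if (ts[t] == 1) {
        int j = aspect[t], v = word[t];
        n_aaw[i + A * (j + Y * v)]++; n_aaw_sum[i + A * j]++;
      }
  }

  void recount() {
    alloc();
    n_active = 0;
    for (int d = 0; d < D; d++) {
      if (a[d] < 0) continue;
      n_active++;
      n_ail[a[d]]++;
      for (int t = doc_ptr[d]; t < doc_ptr[d + 1]; t++) {
        int st = ts[t];
        ts[t] = -1;            // attach_token expects an unset slot
        attach_token(d, t, st);
      }
    }
  }

  void load_stats(List st) {
    IntegerVector v1 = st["n_ail"], v2 = st["n_doc_topic"], v3 = st["n_doc_ail"],
                  v4 = st["n_doc_top"], v5 = st["n_topic_word"],
                  v6 = st["n_ail_aspect_word"], v7 = st["n_bg_aspect_word"];
    n_ail.assign(v1.begin(), v1.end());
    n_doc_topic.assign(v2.begin(), v2.end());
    n_doc_ail.assign(v3.begin(), v3.end());
    n_doc_top.assign(v4.begin(), v4.end());
    n_tw.assign(v5.begin(), v5.end());
    n_aaw.assign(v6.begin(), v6.end());
    n_bgw.assign(v7.begin(), v7.end());
    n_tw_sum.assign(Z, 0);
    for (int v = 0; v < W; v++)
      for (int k = 0; k < Z; k++) n_tw_sum[k] += n_tw[k + Z * v];
    n_aaw_sum.assign((size_t)A * Y, 0);
    for (int v = 0; v < W; v++)
      for (int j = 0; j < Y; j++)
        for (int i = 0; i < A; i++) n_aaw_sum[i + A * j] += n_aaw[i + A * (j + Y * v)];
    n_bgw_sum.assign(Y, 0);
    for (int v = 0; v < W; v++)
      for (int j = 0; j < Y; j++) n_bgw_sum[j] += n_bgw[j + Y * v];
    n_active = 0;
    for (int d = 0; d < D; d++) if (a[d] >= 0) n_active++;
  }

  List export_stats() {
    IntegerVector ndt(n_doc_topic.begin(), n_doc_topic.end());
    ndt.attr("dim") = IntegerVector::create(D, Z);
    IntegerVector ntw(n_tw.begin(), n_tw.end());
    ntw.attr("dim") = IntegerVector::create(Z, W);
    IntegerVector naw(n_aaw.begin(), n_aaw.end());
    naw.attr("dim") = IntegerVector::create(A, Y, W);
    IntegerVector nbw(n_bgw.begin(), n_bgw.end());
    nbw.attr("dim") = IntegerVector::create(Y, W);
    return List::create(
      _["n_ail"] = IntegerVector(n_ail.begin(), n_ail.end()),
      _["n_doc_topic"] = ndt,
      _["n_doc_ail"] = IntegerVector(n_doc_ail.begin(), n_doc_ail.end()),
      _["n_doc_top"] = IntegerVector(n_doc_top.begin(), n_doc_top.end()),
      _["n_topic_word"] = ntw,
      _["n_ail_aspect_word"] = naw,
      _["n_bg_aspect_word"] = nbw);
  }

  // Log unnormalized p(a_d = i | rest); document d must be detached.
  // Dirichlet-multinomial predictives of the document's ailment tokens are
  // accumulated by the chain rule (all tokens move jointly), in log space.
  void ailment_logprobs(int d, std::vector<double>& lp) {
    int beg = doc_ptr[d], end = doc_ptr[d + 1];
    std::vector<int> extra_sum(Y);
    for (int i = 0; i < A; i++) {
      double l = std::log(n_ail[i] + sigma);
      std::fill(extra_sum.begin(), extra_sum.end(), 0);
      for (int t = beg; t < end; t++) {
        if (ts[t] != 1) continue;
        int j = aspect[t], v = word[t];
        int extra = 0;
        for (int t2 = beg; t2 < t; t2++)
          if (ts[t2] == 1 && aspect[t2] == j && word[t2] == v) extra++;
        l += std::log(n_aaw[i + A * (j + Y * v)] + s[i] * m(i, v) + extra) -
             std::log(n_aaw_sum[i + A * j] + s[i] + extra_sum[j]);
        extra_sum[j]++;
      }
      double as = alpha_sum[i];
      l += lg(as) - lg(as + n_doc_top[d]);
      for (int k = 0; k < Z; k++) {
        int c = n_doc_topic[d + (size_t)D * k];
        if (c > 0) l += lg(alpha(i, k) + c) - lg(alpha(i, k));
      }
      if (ISNAN(l)) stop("non-finite ailment log-probability (ailment %d, doc %d)", i + 1, d + 1);
      lp[i] = l;
    }
  }

  // Unnormalized p(token state | rest) over {BG, AIL, TOP(0..Z-1)};
  // token t (in document d, ailment i = a[d]) must be detached.
  // mask_ail forces pi_d = 0: the AIL entry is zero and the Beta(gamma)
  // factor disappears because the ailment/topic split is never drawn.
  void token_probs(int d, int t, std::vector<double>& p, bool mask_ail) {
    int j = aspect[t], v = word[t], i = a[d];
    p.assign(Z + 2, 0.0);
    p[0] = (1.0 - lambda) * (n_bgw[j + Y * v] + beta) / (n_bgw_sum[j] + W * beta);
    double nA = n_doc_ail[d], nT = n_doc_top[d];
    double fA, fT;
    if (mask_ail) {
      fA = 0.0; fT = 1.0;
    } else {
      double den = nA + nT + 2.0 * gam;
      fA = (nA + gam) / den;
      fT = (nT + gam) / den;
    }
    if (!mask_ail)
      p[1] = lambda * fA * (n_aaw[i + A * (j + Y * v)] + s[i] * m(i, v)) /
             (n_aaw_sum[i + A * j] + s[i]);
    double as = alpha_sum[i];
    for (int k = 0; k < Z; k++)
      p[2 + k] = lambda * fT *
                 (n_doc_topic[d + (size_t)D * k] + alpha(i, k)) / (nT + as) *
                 (n_tw[k + Z * v] + beta) / (n_tw_sum[k] + W * beta);
  }

  // Collapsed log p(w, a, z, x, l | hyperparameters); -Inf possible only when
  // lambda is at {0,1} with states on the wrong side, which callers treat as
  // an error.
  double joint_ll() {
    double ll = lg(A * sigma) - lg(A * sigma + n_active);
    for (int i = 0; i < A; i++) ll += lg(sigma + n_ail[i]) - lg(sigma);
    long nbg = 0, nnon = 0;
    for (int d = 0; d < D; d++) {
      if (a[d] < 0) continue;
      int nA = n_doc_ail[d], nT = n_doc_top[d];
      int Nd = doc_ptr[d + 1] - doc_ptr[d];
      nbg += Nd - nA - nT;
      nnon += nA + nT;
      ll += lg(2.0 * gam) - lg(2.0 * gam + nA + nT) +
            lg(gam + nA) + lg(gam + nT) - 2.0 * lg(gam);
      int i = a[d];
      double as = alpha_sum[i];
      ll += lg(as) - lg(as + nT);
      for (int k = 0; k < Z; k++) {
        int c = n_doc_topic[d + (size_t)D * k];
        if (c > 0) ll += lg(alpha(i, k) + c) - lg(alpha(i, k));
      }
    }
    if (nnon > 0) ll += nnon * std::log(lambda);
    if (nbg > 0) ll += nbg * std::log(1.0 - lambda);
    for (int k = 0; k < Z; k++) {
      ll += lg(W * beta) - lg(W * beta + n_tw_sum[k]);
      for (int v = 0; v < W; v++) {
        int c = n_tw[k + Z * v];
        if (c > 0) ll += lg(beta + c) - lg(beta);
      }
    }
    for (int j = 0; j < Y; j++) {
      ll += lg(W * beta) - lg(W * beta + n_bgw_sum[j]);
      for (int v = 0; v < W; v++) {
        int c = n_bgw[j + Y * v];
        if (c > 0) ll += lg(beta + c) - lg(beta);
      }
    }
    for (int i = 0; i < A; i++)
      for (int j = 0; j < Y; j++) {
        ll += lg(s[i]) - lg(s[i] + n_aaw_sum[i + A * j]);
        for (int v = 0; v < W; v++) {
          int c = n_aaw[i + A * (j + Y * v)];
          if (c > 0) ll += lg(s[i] * m(i, v) + c) - lg(s[i] * m(i, v));
        }
      }
    return ll;
  }

  void sweep(const IntegerVector& docs) {
    std::vector<double> lp(A), p(Z + 2);
    for (int di = 0; di < docs.size(); di++) {
      int d = docs[di];
      detach_ail(d);
      ailment_logprobs(d, lp);
      attach_ail(d, sample_from_log(lp, "ailment conditional"));
      for (int t = doc_ptr[d]; t < doc_ptr[d + 1]; t++) {
        detach_token(d, t);
        token_probs(d, t, p, false);
        attach_token(d, t, sample_linear(p, "token conditional"));
      }
    }
  }

  // Mixed-radix index of the full latent configuration (tiny instances only).
  long long config_index() {
    long long ix = 0;
    for (int d = 0; d < D; d++) if (a[d] >= 0) ix = ix * A + a[d];
    for (int t = 0; t < T; t++) if (ts[t] >= 0) ix = ix * (Z + 2) + ts[t];
    return ix;
  }
};

// [[Rcpp::export]]
List cpp_atam_run(List corpus, IntegerVector a, IntegerVector ts, List priors,
                  Nullable<List> stats, IntegerVector docs, int nsweeps,
                  int ll_every, int tally_burnin, IntegerVector tally,
                  bool do_tally) {
  ATAM mdl;
  mdl.init(corpus, a, ts, priors, stats);
  std::vector<double> lls;
  for (int it = 0; it < nsweeps; it++) {
    mdl.sweep(docs);
    if (ll_every > 0 && ((it + 1) % ll_every == 0)) lls.push_back(mdl.joint_ll());
    if (do_tally && it >= tally_burnin) {
      long long ix = mdl.config_index();
      if (ix < 0 || ix >= tally.size()) stop("configuration index out of tally range");
      tally[ix]++;
    }
    if ((it & 1023) == 1023) Rcpp::checkUserInterrupt();
  }
  return List::create(_["a"] = mdl.a, _["tstate"] = mdl.ts,
                      _["stats"] = mdl.export_stats(),
                      _["loglik"] = NumericVector(lls.begin(), lls.end()),
                      _["tally"] = tally);
}

// [[Rcpp::export]]
NumericVector cpp_ailment_conditional(List corpus, IntegerVector a, IntegerVector ts,
                                      List priors, Nullable<List> stats, int d) {
  ATAM mdl;
  mdl.init(corpus, a, ts, priors, stats);
  if (d < 0 || d >= mdl.D || mdl.a[d] < 0) stop("invalid document index");
  mdl.detach_ail(d);
  std::vector<double> lp(mdl.A);
  mdl.ailment_logprobs(d, lp);
  double mx = lp[0];
  for (double x : lp) if (x > mx) mx = x;
  double tot = 0.0;
  for (size_t q = 0; q < lp.size(); q++) { lp[q] = std::exp(lp[q] - mx); tot += lp[q]; }
  NumericVector out(mdl.A);
  for (int i = 0; i < mdl.A; i++) out[i] = lp[i] / tot;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_token_conditional(List corpus, IntegerVector a, IntegerVector ts,
                                    List priors, Nullable<List> stats, int d, int t,
                                    bool mask_ail) {
  ATAM mdl;
  mdl.init(corpus, a, ts, priors, stats);
  if (d < 0 || d >= mdl.D || mdl.a[d] < 0) stop("invalid document index");
  if (t < mdl.doc_ptr[d] || t >= mdl.doc_ptr[d + 1]) stop("token not in document");
  mdl.detach_token(d, t);
  std::vector<double> p;
  mdl.token_probs(d, t, p, mask_ail);
  double tot = 0.0;
  for (double x : p) {
    if (!R_finite(x)) stop("non-finite token probability");
    tot += x;
  }
  if (tot <= 0.0) stop("zero total token probability");
  NumericVector out(p.size());
  for (size_t q = 0; q < p.size(); q++) out[q] = p[q] / tot;
  return out;
}

// [[Rcpp::export]]
double cpp_atam_joint_ll(List corpus, IntegerVector a, IntegerVector ts, List priors) {
  ATAM mdl;
  mdl.init(corpus, a, ts, priors, R_NilValue);
  return mdl.joint_ll();
}

// [[Rcpp::export]]
List cpp_atam_recount(List corpus, IntegerVector a, IntegerVector ts, List priors) {
  ATAM mdl;
  mdl.init(corpus, a, ts, priors, R_NilValue);
  return mdl.export_stats();
}

// Greedy (or sampled) initialization of newly activated documents from the
// current conditionals: prevalence-only ailment guess, left-to-right token
// states, then a final ailment pass given the chosen token states.
// [[Rcpp::export]]
List cpp_atam_extend(List corpus, IntegerVector a, IntegerVector ts, List priors,
                     Nullable<List> stats, IntegerVector new_docs, bool sample_mode) {
  ATAM mdl;
  mdl.init(corpus, a, ts, priors, stats);
  std::vector<double> lp(mdl.A), p;
  for (int di = 0; di < new_docs.size(); di++) {
    int d = new_docs[di];
    if (d < 0 || d >= mdl.D) stop("invalid document index");
    if (mdl.a[d] >= 0) stop("document %d is already active", d + 1);
    mdl.n_active++;
    mdl.ailment_logprobs(d, lp);  // doc holds no counts yet
    int i0 = sample_mode ? sample_from_log(lp, "ailment conditional")
                         : argmax_vec(lp);
    mdl.attach_ail(d, i0);
    for (int t = mdl.doc_ptr[d]; t < mdl.doc_ptr[d + 1]; t++) {
      mdl.token_probs(d, t, p, false);
      int st = sample_mode ? sample_linear(p, "token conditional") : argmax_vec(p);
      mdl.attach_token(d, t, st);
    }
    mdl.detach_ail(d);
    mdl.ailment_logprobs(d, lp);
    int i1 = sample_mode ? sample_from_log(lp, "ailment conditional")
                         : argmax_vec(lp);
    mdl.attach_ail(d, i1);
  }
  return List::create(_["a"] = mdl.a, _["tstate"] = mdl.ts,
                      _["stats"] = mdl.export_stats());
}

// ------------------------------------------------------------- LDA-bg core

struct LDABG {
  int Z, W, D, T;
  double lambda, beta;
  NumericVector alpha;
  double alpha_sum;
  IntegerVector doc_ptr, word;
  IntegerVector ts;
  std::vector<int> n_doc_topic, n_doc_top, n_tw, n_tw_sum, n_bgw;
  int n_bg_total;

  void init(List corpus, IntegerVector ts_, List hypers, Nullable<List> stats_) {
    doc_ptr = corpus["doc_ptr"];
    word = corpus["word"];
    D = doc_ptr.size() - 1;
    T = word.size();
    Z = as<int>(hypers["Z"]);
    W = as<int>(hypers["W"]);
    lambda = as<double>(hypers["lambda"]);
    beta = as<double>(hypers["beta"]);
    alpha = as<NumericVector>(hypers["alpha"]);
    if (alpha.size() != Z) stop("alpha must have length Z");
    alpha_sum = 0.0;
    for (int k = 0; k < Z; k++) alpha_sum += alpha[k];
    ts = clone(ts_);
    if (stats_.isNotNull()) load_stats(as<List>(stats_)); else recount();
  }

  void attach_token(int d, int t, int st) {
    ts[t] = st;
    int v = word[t];
    if (st == 0) {
      n_bgw[v]++; n_bg_total++;
    } else {
      int k = st - 1;
      n_tw[k + Z * v]++; n_tw_sum[k]++;
      n_doc_topic[d + (size_t)D * k]++; n_doc_top[d]++;
    }
  }

  void detach_token(int d, int t) {
    int st = ts[t], v = word[t];
    if (st == 0) {
      n_bgw[v]--; n_bg_total--;
    } else {
      int k = st - 1;
      n_tw[k + Z * v]--; n_tw_sum[k]--;
      n_doc_topic[d + (size_t)D * k]--; n_doc_top[d]--;
    }
    ts[t] = -1;
  }

  void recount() {
    n_doc_topic.assign((size_t)D * Z, 0);
    n_doc_top.assign(D, 0);
    n_tw.assign((size_t)Z * W, 0);
    n_tw_sum.assign(Z, 0);
    n_bgw.assign(W, 0);
    n_bg_total = 0;
    for (int d = 0; d < D; d++) {
      for (int t = doc_ptr[d]; t < doc_ptr[d + 1]; t++) {
        if (ts[t] < 0) continue;
        int st = ts[t];
        ts[t] = -1;
        attach_token(d, t, st);
      }
    }
  }

  void load_stats(List st) {
    IntegerVector v1 = st["n_doc_topic"], v2 = st["n_doc_top"],
                  v3 = st["n_topic_word"], v4 = st["n_bg_word"];
    n_doc_topic.assign(v1.begin(), v1.end());
    n_doc_top.assign(v2.begin(), v2.end());
    n_tw.assign(v3.begin(), v3.end());
    n_bgw.assign(v4.begin(), v4.end());
    n_tw_sum.assign(Z, 0);
    for (int v = 0; v < W; v++)
      for (int k = 0; k < Z; k++) n_tw_sum[k] += n_tw[k + Z * v];
    n_bg_total = 0;
    for (int v = 0; v < W; v++) n_bg_total += n_bgw[v];
  }

  List export_stats() {
    IntegerVector ndt(n_doc_topic.begin(), n_doc_topic.end());
    ndt.attr("dim") = IntegerVector::create(D, Z);
    IntegerVector ntw(n_tw.begin(), n_tw.end());
    ntw.attr("dim") = IntegerVector::create(Z, W);
    return List::create(
      _["n_doc_topic"] = ndt,
      _["n_doc_top"] = IntegerVector(n_doc_top.begin(), n_doc_top.end()),
      _["n_topic_word"] = ntw,
      _["n_bg_word"] = IntegerVector(n_bgw.begin(), n_bgw.end()));
  }

  void token_probs(int d, int t, std::vector<double>& p) {
    int v = word[t];
    p.assign(Z + 1, 0.0);
    p[0] = (1.0 - lambda) * (n_bgw[v] + beta) / (n_bg_total + W * beta);
    for (int k = 0; k < Z; k++)
      p[1 + k] = lambda *
                 (n_doc_topic[d + (size_t)D * k] + alpha[k]) / (n_doc_top[d] + alpha_sum) *
                 (n_tw[k + Z * v] + beta) / (n_tw_sum[k] + W * beta);
  }

  double joint_ll() {
    double ll = 0.0;
    long nbg = 0, nnon = 0;
    for (int d = 0; d < D; d++) {
      int nT = n_doc_top[d];
      int Nd = doc_ptr[d + 1] - doc_ptr[d];
      if (Nd == 0 || ts[doc_ptr[d]] < 0) continue;  // empty or not yet active
      nbg += Nd - nT;
      nnon += nT;
      ll += lg(alpha_sum) - lg(alpha_sum + nT);
      for (int k = 0; k < Z; k++) {
        int c = n_doc_topic[d + (size_t)D * k];
        if (c > 0) ll += lg(alpha[k] + c) - lg(alpha[k]);
      }
    }
    if (nnon > 0) ll += nnon * std::log(lambda);
    if (nbg > 0) ll += nbg * std::log(1.0 - lambda);
    for (int k = 0; k < Z; k++) {
      ll += lg(W * beta) - lg(W * beta + n_tw_sum[k]);
      for (int v = 0; v < W; v++) {
        int c = n_tw[k + Z * v];
        if (c > 0) ll += lg(beta + c) - lg(beta);
      }
    }
    ll += lg(W * beta) - lg(W * beta + n_bg_total);
    for (int v = 0; v < W; v++)
      if (n_bgw[v] > 0) ll += lg(beta + n_bgw[v]) - lg(beta);
    return ll;
  }

  void sweep(const IntegerVector& docs) {
    std::vector<double> p(Z + 1);
    for (int di = 0; di < docs.size(); di++) {
      int d = docs[di];
      for (int t = doc_ptr[d]; t < doc_ptr[d + 1]; t++) {
        detach_token(d, t);
        token_probs(d, t, p);
        attach_token(d, t, sample_linear(p, "LDA token conditional"));
      }
    }
  }

  long long config_index() {
    long long ix = 0;
    for (int t = 0; t < T; t++) if (ts[t] >= 0) ix = ix * (Z + 1) + ts[t];
    return ix;
  }
};

// [[Rcpp::export]]
List cpp_lda_run(List corpus, IntegerVector ts, List hypers, Nullable<List> stats,
                 IntegerVector docs, int nsweeps, int ll_every, int tally_burnin,
                 IntegerVector tally, bool do_tally) {
  LDABG mdl;
  mdl.init(corpus, ts, hypers, stats);
  std::vector<double> lls;
  for (int it = 0; it < nsweeps; it++) {
    mdl.sweep(docs);
    if (ll_every > 0 && ((it + 1) % ll_every == 0)) lls.push_back(mdl.joint_ll());
    if (do_tally && it >= tally_burnin) {
      long long ix = mdl.config_index();
      if (ix < 0 || ix >= tally.size()) stop("configuration index out of tally range");
      tally[ix]++;
    }
    if ((it & 1023) == 1023) Rcpp::checkUserInterrupt();
  }
  return List::create(_["tstate"] = mdl.ts, _["stats"] = mdl.export_stats(),
                      _["loglik"] = NumericVector(lls.begin(), lls.end()),
                      _["tally"] = tally);
}

// [[Rcpp::export]]
NumericVector cpp_lda_token_conditional(List corpus, IntegerVector ts, List hypers,
                                        Nullable<List> stats, int d, int t) {
  LDABG mdl;
  mdl.init(corpus, ts, hypers, stats);
  if (d < 0 || d >= mdl.D) stop("invalid document index");
  if (t < mdl.doc_ptr[d] || t >= mdl.doc_ptr[d + 1]) stop("token not in document");
  mdl.detach_token(d, t);
  std::vector<double> p;
  mdl.token_probs(d, t, p);
  double tot = 0.0;
  for (double x : p) {
    if (!R_finite(x)) stop("non-finite token probability");
    tot += x;
  }
  if (tot <= 0.0) stop("zero total token probability");
  NumericVector out(p.size());
  for (size_t q = 0; q < p.size(); q++) out[q] = p[q] / tot;
  return out;
}

// [[Rcpp::export]]
double cpp_lda_joint_ll(List corpus, IntegerVector ts, List hypers) {
  LDABG mdl;
  mdl.init(corpus, ts, hypers, R_NilValue);
  return mdl.joint_ll();
}

// [[Rcpp::export]]
List cpp_lda_recount(List corpus, IntegerVector ts, List hypers) {
  LDABG mdl;
  mdl.init(corpus, ts, hypers, R_NilValue);
  return mdl.export_stats();
}
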