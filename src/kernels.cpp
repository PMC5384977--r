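#include <Rcpp.h>
using namespace Rcpp;

// Synthesize one trial's multi-muscle EMG signal.
//
// Baseline: zero-mean Gaussian noise (sd = noise_sd) for every muscle and
// sample. From each active muscle's onset sample, an amplitude-modulated
// Gaussian carrier is added whose SD follows a linear ramp (ramp_n samples)
// up to the muscle's amplitude, then stays at plateau. Uses R's RNG, so
// draws are reproducible under set.seed(); draw order is: full noise matrix
// column-major, then per active muscle (ascending index) the carrier
// segment.
//
// onset_idx: 1-based sample index of each muscle's activation onset
// (NA_INTEGER or > n for inactive/never-active muscles); amps: plateau
// amplitude per muscle (0 = inactive).
// [[Rcpp::export(name = ".cpp_synth_signal")]]
NumericMatrix cpp_synth_signal(int nm, int n, double noise_sd,
                               NumericVector amps, IntegerVector onset_idx,
                               int ramp_n) {
  NumericMatrix sig(nm, n);
  double *p = REAL(sig);
  R_xlen_t total = (R_xlen_t)nm * n;
  for (R_xlen_t i = 0; i < total; i++) p[i] = norm_rand() * noise_sd;
  if (ramp_n < 1) ramp_n = 1;
  for (int m = 0; m < nm; m++) {
    if (amps[m] <= 0.0 || onset_idx[m] == NA_INTEGER) continue;
    int on = onset_idx[m];
    if (on > n) continue;
    if (on < 1) on = 1;
    for (int j = on - 1; j < n; j++) {
      int k = j - (on - 1) + 1;           // 1-based position in the burst
      double env = amps[m] * (k >= ramp_n ? 1.0 : (double)k / ramp_n);
      sig(m, j) += env * norm_rand();
    }
  }
  return sig;
}

// Rectify + (optional) centered running mean with shrinking edge windows +
// baseline mean/SD threshold + first sustained strict threshold crossing.
//
// signal: muscles x samples. Baseline samples are columns b_lo..b_hi
// (1-based, inclusive); the search starts at column p_lo and a crossing may
// start at most at column p_lo + max_start - 1; a crossing needs d_samp
// consecutive samples strictly above threshold (run may extend past the
// search limit, within the signal). w: odd smoothing window length in
// samples (<= 1 disables). Returns baseline mean, SD (n-1), threshold and
// the 1-based column index of the detected crossing start (0 = none).
// [[Rcpp::export(name = ".cpp_detect_kernel")]]
List cpp_detect_kernel(NumericMatrix signal, int b_lo, int b_hi, int p_lo,
                       double k_sd, int w, int d_samp, int max_start) {
  int nm = signal.nrow(), n = signal.ncol();
  NumericVector bmean(nm), bsd(nm), thr(nm);
  IntegerVector rt_idx(nm);
  std::vector<double> proc(n);
  int half = (w - 1) / 2;
  int nb = b_hi - b_lo + 1;
  // rectify in one sequential pass over the column-major input, writing
  // muscle-contiguous rows (cache-friendly for the per-muscle scans below)
  std::vector<double> rect_all((size_t)nm * n);
  const double *in = REAL(signal);
  for (int j = 0; j < n; j++)
    for (int m = 0; m < nm; m++)
      rect_all[(size_t)m * n + j] = std::fabs(in[(size_t)j * nm + m]);
  for (int m = 0; m < nm; m++) {
    const double *rect = rect_all.data() + (size_t)m * n;
    if (w > 1) {
      // prefix sums for O(1) window means, edges shrink
      std::vector<double> cs(n + 1, 0.0);
      for (int j = 0; j < n; j++) cs[j + 1] = cs[j] + rect[j];
      for (int j = 0; j < n; j++) {
        int lo = j - half < 0 ? 0 : j - half;
        int hi = j + half > n - 1 ? n - 1 : j + half;
        proc[j] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
      }
    } else {
      std::copy(rect, rect + n, proc.begin());
    }
    double s = 0.0, ss = 0.0;
    for (int j = b_lo - 1; j < b_hi; j++) s += proc[j];
    double mu = s / nb;
    for (int j = b_lo - 1; j < b_hi; j++) ss += (proc[j] - mu) * (proc[j] - mu);
    bmean[m] = mu;
    bsd[m] = nb > 1 ? std::sqrt(ss / (nb - 1)) : 0.0;
    thr[m] = mu + k_sd * bsd[m];
    rt_idx[m] = 0;
    int limit_start = p_lo - 1 + max_start;   // last allowed 0-based start + 1
    int run = 0;
    for (int j = p_lo - 1; j < n; j++) {
      if (proc[j] > thr[m]) {
        run++;
        if (run >= d_samp) {
          int start = j - d_samp + 1;
          if (start < limit_start) {
            rt_idx[m] = start + 1;
            break;
          } else {
            run = 0;  // run began past the search limit; no earlier start can follow
            break;
          }
        }
      } else {
        run = 0;
        if (j >= limit_start + d_samp) break;  // no admissible start can complete
      }
    }
    // note: a run that starts within the limit may complete after it
  }
  return List::create(_["baseline_mean"] = bmean, _["baseline_sd"] = bsd,
                      _["threshold"] = thr, _["rt_idx"] = rt_idx);
}
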