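#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Continuous-time event simulation of nucleosome sliding by a dimeric
// remodeller with flank-length sensing.
//
// State per molecule: left flank length l (bp), 0 <= l <= total_flank; the
// right flank is total_flank - l, so flank conservation holds by
// construction. Stepping toward side i (shrinking flank i by 1 bp) occurs at
// rate k_step0 * sigma(l_i) + k_leak/2, where sigma is a logistic sensing
// function with midpoint s_sense and width sense_width: motion toward a side
// is permitted in proportion to that side's flank being sensed as long, so
// the net drift k_step0 * (sigma(l_long) - sigma(l_short)) grows the shorter
// flank. Leaving a preferred position (displacement from the start a
// multiple of well_period) is slowed by exp(-well_depth). Stepping requires
// a sliding-productive dimer (at least one active motor in the productive
// orientation) and stops at arrest; ATP hydrolysis occurs at
// n_active * k_atp per molecule regardless, with every step debiting the
// same ledger (futile rate = max(0, k_atp_total - step rates)). On stepping
// onto a well other than the starting one, a molecule whose two flanks both
// satisfy sigma >= arrest_sigma arrests with probability p_arrest: arrest
// models the progressive uncoupling that terminates a productive sliding
// run, and a molecule "arrested" where it started would be
// indistinguishable from one that never engaged.
//
// Uses R's RNG so runs are reproducible under set.seed().

static inline double sigma_sense(double l, double s, double w) {
  return 1.0 / (1.0 + std::exp(-(l - s) / w));
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n_mol, NumericVector out_times,
              int a0, int total_flank,
              double k_step0, double s_sense, double sense_width,
              double k_atp_total, double p_arrest, double arrest_sigma,
              int well_period, double well_depth, double k_leak,
              double p_productive) {
  const int n_out = out_times.size();
  IntegerMatrix disp(n_mol, n_out);
  NumericMatrix atp(n_mol, n_out);
  IntegerVector steps(n_mol);
  LogicalVector arrested(n_mol), productive(n_mol);
  NumericVector arrest_time(n_mol, NA_REAL);
  IntegerVector final_l(n_mol);
  const double t_end = out_times[n_out - 1];
  const double wfac = std::exp(-well_depth);

  for (int m = 0; m < n_mol; ++m) {
    int l = a0;
    double t = 0.0, a = 0.0; // a = ATP count
    long nstep = 0;
    bool prod = unif_rand() < p_productive;
    bool arr = false;
    double t_arr = NA_REAL;
    int oi = 0;

    while (oi < n_out) {
      double rl = 0.0, rr = 0.0;
      if (prod && !arr) {
        double w = (((l - a0) % well_period) == 0) ? wfac : 1.0;
        if (l > 0)
          rl = (k_step0 * sigma_sense((double)l, s_sense, sense_width) +
                0.5 * k_leak) * w;
        if (l < total_flank)
          rr = (k_step0 * sigma_sense((double)(total_flank - l), s_sense,
                                      sense_width) + 0.5 * k_leak) * w;
      }
      double fut = k_atp_total - rl - rr;
      if (fut < 0.0) fut = 0.0;

      if (!prod || arr || (rl + rr) == 0.0) {
        // no more position events: fill remaining outputs; ATP accrues as a
        // Poisson count at k_atp_total (uncoupled hydrolysis continues)
        while (oi < n_out) {
          double dt = out_times[oi] - t;
          if (k_atp_total > 0.0 && dt > 0.0)
            a += R::rpois(k_atp_total * dt);
          t = out_times[oi];
          disp(m, oi) = l - a0;
          atp(m, oi) = a;
          ++oi;
        }
        break;
      }

      double R = rl + rr + fut;
      double dt = exp_rand() / R;
      double t_new = t + dt;
      while (oi < n_out && out_times[oi] <= t_new) {
        disp(m, oi) = l - a0;
        atp(m, oi) = a;
        ++oi;
      }
      if (oi >= n_out || t_new > t_end) break;
      t = t_new;
      a += 1.0; // every event hydrolyses one ATP
      double u = unif_rand() * R;
      if (u < rl || u < rl + rr) {
        l += (u < rl) ? -1 : +1;
        ++nstep;
        if (l != a0 && (((l - a0) % well_period) == 0) &&
            sigma_sense((double)l, s_sense, sense_width) >= arrest_sigma &&
            sigma_sense((double)(total_flank - l), s_sense, sense_width) >=
                arrest_sigma &&
            unif_rand() < p_arrest) {
          arr = true;
          t_arr = t;
        }
      }
      // else: futile hydrolysis, no movement
    }
    steps[m] = (int)nstep;
    arrested[m] = arr;
    productive[m] = prod;
    arrest_time[m] = t_arr;
    final_l[m] = l;
  }

  return List::create(_["disp"] = disp, _["atp"] = atp, _["steps"] = steps,
                      _["arrested"] = arrested, _["productive"] = productive,
                      _["arrest_time"] = arrest_time, _["final_l"] = final_l);
}
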