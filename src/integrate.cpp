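#include <Rcpp.h>
using namespace Rcpp;

// Population order throughout: LA, BAf, BAe, CeAOn, CeAOff.
//
// The vector field is (F(net + eta) - U) / tau per population, with the
// sigmoid F(x) = 1 / (1 + exp(-gain * (x - threshold))). Noise eta is drawn
// i.i.d. per population per step from N(noise_mean, noise_sd) using R's RNG
// (one rnorm(5) block per step, LA first), so an R-level reference loop that
// draws rnorm(5) in the same order reproduces the trajectory bit for bit.

static inline double sigm(double x, double gain, double th) {
  return 1.0 / (1.0 + std::exp(-gain * (x - th)));
}

// [[Rcpp::export]]
List cpp_integrate(NumericVector state,     // length 5
                   NumericVector plastic,   // w_thal_la, w_hip_baf, w_pfc_bae
                   List params,             // CircuitParams as flat list
                   NumericVector inputs,    // i_thal, i_hip, i_pfc
                   int n_steps,
                   double dt,
                   bool noise_on,
                   double noise_mean,
                   double noise_sd,
                   int readout_steps,       // terminal window for u_on readout
                   bool record) {
  const double w_la_baf   = params["w_la_baf"];
  const double w_ba_inhib = params["w_ba_inhib"];
  const double w_la_inhib = params["w_la_inhib"];
  const double w_baf_cea  = params["w_baf_cea"];
  const double w_la_cea   = params["w_la_cea"];
  const double w_bae_cea  = params["w_bae_cea"];
  const double w_cea_inhib= params["w_cea_inhib"];
  const double dr_ba      = params["dr_ba"];
  const double dr_la      = params["dr_la"];
  const double dr_cea     = params["dr_cea"];
  const double tau        = params["tau"];
  const double gain       = params["gain"];
  const double th         = params["threshold"];

  double la = state[0], baf = state[1], bae = state[2],
         on = state[3], off = state[4];
  const double wt = plastic[0], wh = plastic[1], wp = plastic[2];
  const double it = inputs[0], ih = inputs[1], ip = inputs[2];

  NumericVector acc(5);
  double ro_acc = 0.0;
  int ro_n = 0;
  NumericMatrix traj;
  if (record) traj = NumericMatrix(n_steps, 5);

  for (int s = 0; s < n_steps; ++s) {
    double e0 = 0, e1 = 0, e2 = 0, e3 = 0, e4 = 0;
    if (noise_on) {
      NumericVector eta = rnorm(5, noise_mean, noise_sd);
      e0 = eta[0]; e1 = eta[1]; e2 = eta[2]; e3 = eta[3]; e4 = eta[4];
    }
    const double n_la  = -w_la_inhib * la + wt * it + dr_la + e0;
    const double n_baf = -w_ba_inhib * bae + w_la_baf * la + wh * ih + dr_ba + e1;
    const double n_bae = -w_ba_inhib * baf + wp * ip + dr_ba + e2;
    const double n_on  =  w_baf_cea * baf + w_la_cea * la - w_cea_inhib * off + dr_cea + e3;
    const double n_off =  w_bae_cea * bae - w_cea_inhib * on + dr_cea + e4;

    // dt * ((F - U) / tau), association matching the R reference step
    la  += dt * ((sigm(n_la,  gain, th) - la)  / tau);
    baf += dt * ((sigm(n_baf, gain, th) - baf) / tau);
    bae += dt * ((sigm(n_bae, gain, th) - bae) / tau);
    on  += dt * ((sigm(n_on,  gain, th) - on)  / tau);
    off += dt * ((sigm(n_off, gain, th) - off) / tau);

    // sigmoid-bounded attractor; overshoot is a discretisation artifact
    la  = std::min(1.0, std::max(0.0, la));
    baf = std::min(1.0, std::max(0.0, baf));
    bae = std::min(1.0, std::max(0.0, bae));
    on  = std::min(1.0, std::max(0.0, on));
    off = std::min(1.0, std::max(0.0, off));

    acc[0] += la; acc[1] += baf; acc[2] += bae; acc[3] += on; acc[4] += off;
    if (s >= n_steps - readout_steps) { ro_acc += on; ++ro_n; }
    if (record) {
      traj(s, 0) = la; traj(s, 1) = baf; traj(s, 2) = bae;
      traj(s, 3) = on; traj(s, 4) = off;
    }
  }

  NumericVector fin = NumericVector::create(la, baf, bae, on, off);
  NumericVector mean_act(5);
  if (n_steps > 0) for (int k = 0; k < 5; ++k) mean_act[k] = acc[k] / n_steps;
  else mean_act = clone(fin);

  List out = List::create(
    _["state"]   = fin,
    _["mean"]    = mean_act,
    _["readout"] = ro_n > 0 ? ro_acc / ro_n : on);
  if (record) out["trajectory"] = traj;
  return out;
}
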