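// Actor-critic PPO variant with a non-bootstrapped single-step RPE and
// n-step advantage accumulation, trained in a 2D arena with a biased
// discrete action space. Single-threaded; all randomness comes from R's RNG
// so runs are bit-reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

const int N_ACTIONS = 256;
const int N_NOOP = 192;
const double ZONE_HALF = 0.2;
const double BOUND = 1.0;

struct ActionTable {
  std::vector<double> dx, dy;
  std::vector<int> dir; // direction index 0..7 (45-degree steps), -1 for no-op
  ActionTable() : dx(N_ACTIONS, 0.0), dy(N_ACTIONS, 0.0), dir(N_ACTIONS, -1) {
    int k = N_NOOP;
    for (int d = 0; d < 8; ++d) {
      double deg = 45.0 * d;
      double lo, hi;
      if (d % 2 == 0) { lo = 0.216; hi = 0.720; }            // cardinal
      else if (deg == 45.0 || deg == 225.0) { lo = 0.072; hi = 0.240; }
      else { lo = 0.360; hi = 1.200; }                        // 135, 315
      for (int s = 0; s < 8; ++s) {
        double mag = lo + (hi - lo) * s / 7.0;
        double th = deg * M_PI / 180.0;
        dx[k] = mag * std::cos(th);
        dy[k] = mag * std::sin(th);
        dir[k] = d;
        ++k;
      }
    }
  }
};

// movement classes
enum MClass { M_NONE = 0, M_TOWARD = 1, M_LATERAL = 2, M_AWAY = 3, M_GOAL = 4 };

bool in_zone(double x, double y) {
  return std::fabs(x) <= ZONE_HALF && std::fabs(y) <= ZONE_HALF;
}

// infinite ray from (px,py) along (dx,dy) vs the closed zone square
bool ray_hits_zone(double px, double py, double dx, double dy) {
  double tmin = -std::numeric_limits<double>::infinity();
  double tmax = std::numeric_limits<double>::infinity();
  double p[2] = {px, py}, d[2] = {dx, dy};
  for (int ax = 0; ax < 2; ++ax) {
    if (std::fabs(d[ax]) < 1e-15) {
      if (p[ax] < -ZONE_HALF || p[ax] > ZONE_HALF) return false;
    } else {
      double t1 = (-ZONE_HALF - p[ax]) / d[ax];
      double t2 = ( ZONE_HALF - p[ax]) / d[ax];
      tmin = std::max(tmin, std::min(t1, t2));
      tmax = std::min(tmax, std::max(t1, t2));
    }
  }
  return tmax >= std::max(tmin, 0.0);
}

int classify_move(double px, double py, double nx, double ny) {
  double rx = nx - px, ry = ny - py;
  if (rx == 0.0 && ry == 0.0) return M_NONE;
  if (in_zone(nx, ny)) return M_GOAL;
  double dp = std::sqrt(px * px + py * py);
  double dn = std::sqrt(nx * nx + ny * ny);
  if (dn >= dp) return M_AWAY;
  if (ray_hits_zone(px, py, rx, ry)) return M_TOWARD;
  return M_LATERAL;
}

double clampd(double v, double lo, double hi) {
  return std::min(std::max(v, lo), hi);
}

// ---------------------------------------------------------------------------
// network

struct Net {
  std::vector<mat> W;  // trunk weights
  std::vector<vec> b;
  mat Wp; vec bp;      // policy head (N_ACTIONS x H)
  mat Wv; vec bv;      // value head (1 x H)
};

double runif01() { return R::unif_rand(); }

mat init_mat(int nr, int nc) {
  double k = 1.0 / std::sqrt((double)nc);
  mat m(nr, nc);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (2.0 * runif01() - 1.0) * k;
  return m;
}
vec init_vec(int n, int fan_in) {
  double k = 1.0 / std::sqrt((double)fan_in);
  vec v(n);
  for (int i = 0; i < n; ++i) v(i) = (2.0 * runif01() - 1.0) * k;
  return v;
}

Net init_net(const std::vector<int>& hidden) {
  Net net;
  int in = 2;
  for (size_t l = 0; l < hidden.size(); ++l) {
    net.W.push_back(init_mat(hidden[l], in));
    net.b.push_back(init_vec(hidden[l], in));
    in = hidden[l];
  }
  net.Wp = init_mat(N_ACTIONS, in); net.bp = init_vec(N_ACTIONS, in);
  net.Wv = init_mat(1, in);         net.bv = init_vec(1, in);
  return net;
}

struct Fwd {
  std::vector<mat> h;  // activations per layer (post-relu), h[0] = input
  mat probs;           // N_ACTIONS x B
  rowvec value;        // 1 x B
};

Fwd forward(const Net& net, const mat& X) {
  Fwd f;
  f.h.push_back(X);
  mat cur = X;
  for (size_t l = 0; l < net.W.size(); ++l) {
    cur = net.W[l] * cur;
    cur.each_col() += net.b[l];
    cur.transform([](double v) { return v > 0.0 ? v : 0.0; });
    f.h.push_back(cur);
  }
  mat logits = net.Wp * cur;
  logits.each_col() += net.bp;
  logits.each_row() -= max(logits, 0);
  mat e = exp(logits);
  f.probs = e.each_row() / sum(e, 0);
  mat v = net.Wv * cur;
  v.each_col() += net.bv;
  f.value = v.row(0);
  return f;
}

struct Adam {
  std::vector<mat> mW, vW; std::vector<vec> mb, vb;
  mat mWp, vWp; vec mbp, vbp; mat mWv, vWv; vec mbv, vbv;
  long t = 0;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  Adam(const Net& n, double lr_) : lr(lr_) {
    for (auto& w : n.W) { mW.push_back(zeros<mat>(size(w))); vW.push_back(zeros<mat>(size(w))); }
    for (auto& x : n.b) { mb.push_back(zeros<vec>(size(x))); vb.push_back(zeros<vec>(size(x))); }
    mWp = zeros<mat>(size(n.Wp)); vWp = zeros<mat>(size(n.Wp));
    mbp = zeros<vec>(size(n.bp)); vbp = zeros<vec>(size(n.bp));
    mWv = zeros<mat>(size(n.Wv)); vWv = zeros<mat>(size(n.Wv));
    mbv = zeros<vec>(size(n.bv)); vbv = zeros<vec>(size(n.bv));
  }
  // single fused pass per parameter block (bias-corrected Adam)
  template <class T>
  void upd(T& w, T& m, T& v, const T& g, double c1, double c2) {
    const double a1 = 1.0 - b1, a2 = 1.0 - b2;
    const double step = lr / c1, isc2 = 1.0 / std::sqrt(c2);
    double* pw = w.memptr(); double* pm = m.memptr(); double* pv = v.memptr();
    const double* pg = g.memptr();
    const uword n = w.n_elem;
    for (uword i = 0; i < n; ++i) {
      pm[i] = b1 * pm[i] + a1 * pg[i];
      pv[i] = b2 * pv[i] + a2 * pg[i] * pg[i];
      pw[i] -= step * pm[i] / (std::sqrt(pv[i]) * isc2 + eps);
    }
  }
};

struct Grads {
  std::vector<mat> gW; std::vector<vec> gb;
  mat gWp; vec gbp; mat gWv; vec gbv;
  double sqnorm() const {
    double s = 0;
    for (auto& g : gW) s += accu(square(g));
    for (auto& g : gb) s += accu(square(g));
    s += accu(square(gWp)) + accu(square(gbp));
    s += accu(square(gWv)) + accu(square(gbv));
    return s;
  }
  void scale(double c) {
    for (auto& g : gW) g *= c;
    for (auto& g : gb) g *= c;
    gWp *= c; gbp *= c; gWv *= c; gbv *= c;
  }
};

Grads backward(const Net& net, const Fwd& f, const mat& gLogits, const rowvec& gV) {
  Grads g;
  const mat& hL = f.h.back();
  g.gWp = gLogits * hL.t();
  g.gbp = sum(gLogits, 1);
  g.gWv = gV * hL.t();
  g.gbv = vec(1); g.gbv(0) = accu(gV);
  mat gh = net.Wp.t() * gLogits + net.Wv.t() * gV;
  g.gW.resize(net.W.size()); g.gb.resize(net.W.size());
  for (int l = (int)net.W.size() - 1; l >= 0; --l) {
    mat gz = gh % conv_to<mat>::from(f.h[l + 1] > 0.0);
    g.gW[l] = gz * f.h[l].t();
    g.gb[l] = sum(gz, 1);
    if (l > 0) gh = net.W[l].t() * gz;
  }
  return g;
}

void adam_step(Net& net, Adam& ad, Grads& g, double max_norm) {
  double nrm = std::sqrt(g.sqnorm());
  if (max_norm > 0 && nrm > max_norm) g.scale(max_norm / nrm);
  ad.t += 1;
  double c1 = 1.0 - std::pow(ad.b1, (double)ad.t);
  double c2 = 1.0 - std::pow(ad.b2, (double)ad.t);
  for (size_t l = 0; l < net.W.size(); ++l) {
    ad.upd(net.W[l], ad.mW[l], ad.vW[l], g.gW[l], c1, c2);
    ad.upd(net.b[l], ad.mb[l], ad.vb[l], g.gb[l], c1, c2);
  }
  ad.upd(net.Wp, ad.mWp, ad.vWp, g.gWp, c1, c2);
  ad.upd(net.bp, ad.mbp, ad.vbp, g.gbp, c1, c2);
  ad.upd(net.Wv, ad.mWv, ad.vWv, g.gWv, c1, c2);
  ad.upd(net.bv, ad.mbv, ad.vbv, g.gbv, c1, c2);
}

Rcpp::List net_to_list(const Net& net) {
  Rcpp::List W(net.W.size()), b(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    W[l] = net.W[l];
    b[l] = net.b[l];
  }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b,
                            Rcpp::Named("Wp") = net.Wp, Rcpp::Named("bp") = net.bp,
                            Rcpp::Named("Wv") = net.Wv, Rcpp::Named("bv") = net.bv);
}

Net net_from_list(const Rcpp::List& l) {
  Net net;
  Rcpp::List W = l["W"], b = l["b"];
  for (int i = 0; i < W.size(); ++i) {
    net.W.push_back(Rcpp::as<mat>(W[i]));
    net.b.push_back(Rcpp::as<vec>(b[i]));
  }
  net.Wp = Rcpp::as<mat>(l["Wp"]); net.bp = Rcpp::as<vec>(l["bp"]);
  net.Wv = Rcpp::as<mat>(l["Wv"]); net.bv = Rcpp::as<vec>(l["bv"]);
  return net;
}

// schedule codes: 0 standard, 1 interleaved, 2 split
double goal_reward(int schedule, bool rewarded, double nx,
                   double r_std, double r_lo, double r_hi) {
  if (schedule == 0) return r_std;
  if (schedule == 1) return rewarded ? r_std : 0.0;
  return nx < 0 ? r_lo : r_hi;
}

struct EpisodeRec {
  int steps = 0, success = 0, rewarded = 1, goal_side = 0, n_pregoal = 0;
  double reward = 0.0, v_goal = NA_REAL, rpe_goal = NA_REAL,
         pregoal_rpe_mean = NA_REAL;
};

struct Rollout {
  std::vector<vec> states;   // state at each included step
  std::vector<int> actions;
  std::vector<double> logp, value, reward, delta;
  std::vector<int> cls;
};

int sample_action(const vec& p) {
  double u = runif01(), c = 0.0;
  for (int a = 0; a < N_ACTIONS; ++a) {
    c += p(a);
    if (u <= c) return a;
  }
  return N_ACTIONS - 1;
}

EpisodeRec run_episode(Net& net, const ActionTable& tab, int schedule,
                       int max_steps, double r_std, double r_lo, double r_hi,
                       double p_rew, Rollout* roll) {
  EpisodeRec rec;
  double px, py;
  do {
    px = 2.0 * runif01() - 1.0;
    py = 2.0 * runif01() - 1.0;
  } while (in_zone(px, py));
  bool rewarded = schedule == 1 ? (runif01() < p_rew) : true;
  rec.rewarded = rewarded ? 1 : 0;

  double pregoal_sum = 0.0;
  for (int st = 0; st < max_steps; ++st) {
    vec x(2); x(0) = px; x(1) = py;
    Fwd f = forward(net, x);
    int a = sample_action(f.probs.col(0));
    double nx = clampd(px + tab.dx[a], -BOUND, BOUND);
    double ny = clampd(py + tab.dy[a], -BOUND, BOUND);
    int cls = classify_move(px, py, nx, ny);
    double r = cls == M_GOAL
      ? goal_reward(schedule, rewarded, nx, r_std, r_lo, r_hi) : 0.0;
    rec.steps = st + 1;
    bool included = cls == M_TOWARD || cls == M_LATERAL || cls == M_GOAL;
    if (included) {
      double v = f.value(0);
      double d = r - v;
      if (roll) {
        roll->states.push_back(x);
        roll->actions.push_back(a);
        roll->logp.push_back(std::log(f.probs(a, 0) + 1e-300));
        roll->value.push_back(v);
        roll->reward.push_back(r);
        roll->delta.push_back(d);
        roll->cls.push_back(cls);
      }
      if (cls == M_GOAL) {
        rec.v_goal = v;
        rec.rpe_goal = d;
        rec.goal_side = nx < 0 ? -1 : 1;
      } else {
        pregoal_sum += d;
        rec.n_pregoal += 1;
      }
    }
    px = nx; py = ny;
    if (cls == M_GOAL) {
      rec.success = 1;
      rec.reward = r;
      break;
    }
  }
  if (rec.n_pregoal > 0) rec.pregoal_rpe_mean = pregoal_sum / rec.n_pregoal;
  return rec;
}

void ppo_update_window(Net& net, Adam& ad, const Rollout& roll,
                       int i0, int i1, // inclusive window over included steps
                       const std::vector<double>& G, int value_target,
                       double gl, double clip_eps, double value_coef,
                       double entropy_coef, double max_norm, int epochs,
                       int episode_idx) {
  int B = i1 - i0 + 1;
  mat X(2, B);
  for (int i = 0; i < B; ++i) X.col(i) = roll.states[i0 + i];
  // advantages: within-window truncated (gamma*lambda)-discounted sums
  vec A(B);
  for (int i = 0; i < B; ++i) {
    double s = 0.0, w = 1.0;
    for (int k = i; k < B; ++k) { s += w * roll.delta[i0 + k]; w *= gl; }
    A(i) = s;
  }
  // critic regression target: advantage-corrected rollout value (GAE
  // return, value_target 0) or within-trial discounted empirical return (1)
  vec tgt(B);
  for (int i = 0; i < B; ++i)
    tgt(i) = value_target == 0 ? roll.value[i0 + i] + A(i) : G[i0 + i];
  for (int ep = 0; ep < epochs; ++ep) {
    Fwd f = forward(net, X);
    mat gLogits(N_ACTIONS, B, fill::zeros);
    rowvec gV(B);
    double invB = 1.0 / B;
    for (int i = 0; i < B; ++i) {
      int a = roll.actions[i0 + i];
      double lp = std::log(f.probs(a, i) + 1e-300);
      double ratio = std::exp(lp - roll.logp[i0 + i]);
      if (!std::isfinite(ratio))
        Rcpp::stop("non-finite probability ratio at episode %d", episode_idx);
      double rc = clampd(ratio, 1.0 - clip_eps, 1.0 + clip_eps);
      bool unclipped_min = ratio * A(i) <= rc * A(i);
      vec col = gLogits.col(i);
      if (unclipped_min) {
        // d/dlogits of -(1/B) ratio*A = -(A*ratio/B) * (onehot - p)
        double c = -A(i) * ratio * invB;
        col = c * (-f.probs.col(i));
        col(a) += c;
      }
      if (entropy_coef > 0) {
        vec p = f.probs.col(i);
        vec lpv = log(p + 1e-300);
        double H = -dot(p, lpv);
        col += (entropy_coef * invB) * (p % (lpv + H));
      }
      gLogits.col(i) = col;
      gV(i) = 2.0 * value_coef * (f.value(i) - tgt(i)) * invB;
    }
    Grads g = backward(net, f, gLogits, gV);
    if (!std::isfinite(g.sqnorm()))
      Rcpp::stop("non-finite gradient at episode %d", episode_idx);
    adam_step(net, ad, g, max_norm);
  }
}

Rcpp::DataFrame recs_to_df(const std::vector<EpisodeRec>& recs) {
  int n = recs.size();
  Rcpp::IntegerVector episode(n), steps(n), success(n), rewarded(n),
      goal_side(n), n_pregoal(n);
  Rcpp::NumericVector reward(n), v_goal(n), rpe_goal(n), pregoal(n);
  for (int i = 0; i < n; ++i) {
    episode[i] = i + 1;
    steps[i] = recs[i].steps; success[i] = recs[i].success;
    rewarded[i] = recs[i].rewarded; goal_side[i] = recs[i].goal_side;
    n_pregoal[i] = recs[i].n_pregoal; reward[i] = recs[i].reward;
    v_goal[i] = recs[i].v_goal; rpe_goal[i] = recs[i].rpe_goal;
    pregoal[i] = recs[i].pregoal_rpe_mean;
  }
  return Rcpp::DataFrame::create(
      Rcpp::Named("episode") = episode, Rcpp::Named("steps") = steps,
      Rcpp::Named("success") = success, Rcpp::Named("rewarded") = rewarded,
      Rcpp::Named("goal_side") = goal_side, Rcpp::Named("reward") = reward,
      Rcpp::Named("v_goal") = v_goal, Rcpp::Named("rpe_goal") = rpe_goal,
      Rcpp::Named("pregoal_rpe_mean") = pregoal,
      Rcpp::Named("n_pregoal") = n_pregoal);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_train_ppo(int schedule, int n_step, int episodes,
                         int naive_episodes, Rcpp::IntegerVector hidden,
                         double lr, double gamma, double lambda,
                         double clip_eps, double max_grad_norm,
                         double value_coef, double entropy_coef,
                         int update_epochs, int max_steps,
                         double reward_standard, double reward_split_low,
                         double reward_split_high,
                         double reward_interleaved_prob, int value_target) {
  Rcpp::RNGScope scope;
  ActionTable tab;
  std::vector<int> hid(hidden.begin(), hidden.end());
  Net net = init_net(hid);
  Rcpp::List naive_params = net_to_list(net);
  Adam ad(net, lr);

  std::vector<EpisodeRec> naive_recs;
  for (int e = 0; e < naive_episodes; ++e)
    naive_recs.push_back(run_episode(net, tab, schedule, max_steps,
                                     reward_standard, reward_split_low,
                                     reward_split_high,
                                     reward_interleaved_prob, nullptr));

  double gl = gamma * lambda;
  std::vector<EpisodeRec> recs;
  for (int e = 0; e < episodes; ++e) {
    Rollout roll;
    EpisodeRec rec = run_episode(net, tab, schedule, max_steps,
                                 reward_standard, reward_split_low,
                                 reward_split_high, reward_interleaved_prob,
                                 &roll);
    recs.push_back(rec);
    int m = roll.delta.size();
    if (m == 0) continue;
    // within-trial discounted empirical return over included steps
    std::vector<double> G(m);
    double g = 0.0;
    for (int i = m - 1; i >= 0; --i) {
      g = roll.reward[i] + gamma * g;
      G[i] = g;
    }
    for (int i0 = 0; i0 < m; i0 += n_step) {
      int i1 = std::min(i0 + n_step, m) - 1;
      ppo_update_window(net, ad, roll, i0, i1, G, value_target, gl, clip_eps,
                        value_coef, entropy_coef, max_grad_norm, update_epochs,
                        e + 1);
    }
    if ((e & 63) == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("params") = net_to_list(net),
      Rcpp::Named("naive_params") = naive_params,
      Rcpp::Named("episodes") = recs_to_df(recs),
      Rcpp::Named("naive_episodes") = recs_to_df(naive_recs));
}

// Batch forward pass through a parameter list; X is n x 2 (rows = states).
// [[Rcpp::export]]
Rcpp::List cpp_forward(Rcpp::List params, const arma::mat& X) {
  Net net = net_from_list(params);
  Fwd f = forward(net, X.t());
  return Rcpp::List::create(
      Rcpp::Named("value") = Rcpp::NumericVector(f.value.begin(), f.value.end()),
      Rcpp::Named("probs") = mat(f.probs.t()),
      Rcpp::Named("hidden") = mat(f.h.back().t()));
}

// Evaluate frozen parameters for `episodes` rollouts (no updates).
// [[Rcpp::export]]
Rcpp::DataFrame cpp_evaluate_policy(Rcpp::List params, int schedule,
                                    int episodes, int max_steps,
                                    double reward_standard,
                                    double reward_split_low,
                                    double reward_split_high,
                                    double reward_interleaved_prob) {
  Rcpp::RNGScope scope;
  ActionTable tab;
  Net net = net_from_list(params);
  std::vector<EpisodeRec> recs;
  for (int e = 0; e < episodes; ++e)
    recs.push_back(run_episode(net, tab, schedule, max_steps, reward_standard,
                               reward_split_low, reward_split_high,
                               reward_interleaved_prob, nullptr));
  return recs_to_df(recs);
}

// Single environment transition, for equivalence tests against the R arena.
// [[Rcpp::export]]
Rcpp::List cpp_env_transition(double px, double py, int action_id,
                              int schedule, bool rewarded,
                              double reward_standard, double reward_split_low,
                              double reward_split_high) {
  if (action_id < 0 || action_id > 255)
    Rcpp::stop("action_id must be in [0, 255]");
  ActionTable tab;
  double nx = clampd(px + tab.dx[action_id], -BOUND, BOUND);
  double ny = clampd(py + tab.dy[action_id], -BOUND, BOUND);
  int cls = classify_move(px, py, nx, ny);
  double r = cls == M_GOAL
    ? goal_reward(schedule, rewarded, nx, reward_standard, reward_split_low,
                  reward_split_high) : 0.0;
  return Rcpp::List::create(
      Rcpp::Named("next_pos") = Rcpp::NumericVector::create(nx, ny),
      Rcpp::Named("movement_class") = cls, Rcpp::Named("reward") = r);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_action_table() {
  ActionTable tab;
  Rcpp::NumericMatrix m(N_ACTIONS, 3);
  for (int a = 0; a < N_ACTIONS; ++a) {
    m(a, 0) = tab.dx[a]; m(a, 1) = tab.dy[a]; m(a, 2) = tab.dir[a];
  }
  return m;
}
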