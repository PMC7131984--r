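// Closed-loop session simulator: task-engine FSM coupled to the synthetic
// mouse at the tick rate.  This is a compiled twin of the pure-R reference
// (engine_step / agent_step): it consumes R's RNG in exactly the same order,
// so a short session run through either path is bit-identical.  Tests rely
// on that equivalence; any change to draw order here must be mirrored in R.

#include <Rcpp.h>
#include <cmath>
#include <cstdarg>
#include <cstdio>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

const double PI = 3.141592653589793238462643383280;

// x %% y as R computes it for doubles (floor-based, result in [0, y))
double r_mod(double x, double y) {
  double tmp = x - std::floor(x / y) * y;
  return tmp - std::floor(tmp / y) * y;
}

double wrap_angle(double a) {
  double w = r_mod(a + PI, 2.0 * PI) - PI;
  if (w == -PI) w = PI;
  return w;
}

// minimum-jerk half-movement, explicit powers (matches the R code bit-for-bit)
double mj(double A, double Dh, double t) {
  double tau = t / Dh;
  double t3 = tau * tau * tau, t4 = t3 * tau, t5 = t4 * tau;
  return A * (10.0 * t3 - 15.0 * t4 + 6.0 * t5);
}

double mj_oab(double A, double D, double s) {
  double half = D / 2.0;
  if (s <= half) return mj(A, half, s < half ? s : half);
  double r = D - s;
  return mj(A, half, r > 0 ? r : 0);
}

struct Plan {
  double direction = 0, amplitude = 0, duration = 0;
  double revup_amp = 0, revup_dur = 0;
  bool has_revup = false;
  double total() const { return duration + (has_revup ? revup_dur : 0.0); }
  double offset(double s) const {
    if (has_revup && s < revup_dur)
      return -mj_oab(revup_amp, revup_dur, s < revup_dur ? s : revup_dur);
    double m = s - (has_revup ? revup_dur : 0.0);
    if (m < 0) m = 0;
    if (m > duration) m = duration;
    return mj_oab(amplitude, duration, m);
  }
};

struct EventRec {
  double t; int kind; int trial; std::string payload;
};

enum EvKind { EV_TRIAL_START, EV_CUE_ON, EV_THRESHOLD_CROSS, EV_REWARD,
              EV_PUNISHMENT_START, EV_ITI_START, EV_BLOCK_SWITCH };
const char* EV_NAMES[] = {"trial_start", "cue_on", "threshold_cross",
                          "reward", "punishment_start", "iti_start",
                          "block_switch"};

enum Phase { PH_ITI, PH_ARMED, PH_PRE_CUE, PH_REWARD_PENDING, PH_TIMEOUT };
enum Variant { V_CENTER_OUT, V_VAO, V_REACTION_TIME, V_BANDIT };

std::string fmt(const char* f, ...) {
  char buf[256];
  va_list ap; va_start(ap, f);
  vsnprintf(buf, sizeof(buf), f, ap);
  va_end(ap);
  return std::string(buf);
}

} // namespace

// [[Rcpp::export]]
List cpp_run_session(List cfg, List agent, int n_ticks) {
  RNGScope scope;

  // ---- configuration ----
  int variant = as<int>(cfg["variant"]);
  int tick = as<int>(cfg["tick_ms"]);
  double amp_threshold = as<double>(cfg["amp_threshold"]);
  int reward_delay = as<int>(cfg["reward_delay_ms"]);
  int iti_ms = as<int>(cfg["iti_ms"]);
  int timeout_ms = as<int>(cfg["timeout_ms"]);
  int cue_lo = as<int>(cfg["cue_lo"]), cue_hi = as<int>(cfg["cue_hi"]);
  int piti_lo = as<int>(cfg["piti_lo"]), piti_hi = as<int>(cfg["piti_hi"]);
  bool punishment = as<bool>(cfg["punishment"]);
  IntegerVector vao_trials = cfg["vao_trials"];
  NumericVector vao_thresholds = cfg["vao_thresholds"];
  NumericVector centers = cfg["centers"];
  double halfwidth = as<double>(cfg["halfwidth"]);
  CharacterVector labels = cfg["labels"];
  NumericVector p0 = cfg["p_reward"];
  int min_block = as<int>(cfg["min_block"]);
  double switch_prob = as<double>(cfg["switch_prob"]);
  double x0 = as<double>(cfg["x0"]), y0 = as<double>(cfg["y0"]);

  // ---- agent parameters ----
  double reach_rate = as<double>(agent["reach_rate"]);
  double amp_mean = as<double>(agent["amp_mean"]);
  double amp_sd = as<double>(agent["amp_sd"]);
  double dur_mean = as<double>(agent["dur_mean"]);
  double dur_sd = as<double>(agent["dur_sd"]);
  NumericVector dir_angles = agent["dir_angles"];
  NumericVector dir_weights = agent["dir_weights"];
  double angular_sd = as<double>(agent["angular_sd"]);
  double rt_mean = as<double>(agent["rt_mean"]);
  double rt_sd = as<double>(agent["rt_sd"]);
  double anticip_prob = as<double>(agent["anticip_prob"]);
  NumericVector anticip_range = agent["anticip_range_ms"];
  double revup_prob = as<double>(agent["revup_prob"]);
  double revup_frac = as<double>(agent["revup_frac"]);
  double jitter_sd = as<double>(agent["jitter_sd"]);
  double blip_rate = as<double>(agent["blip_rate"]);
  double blip_amp = as<double>(agent["blip_amp"]);
  double blip_dur = as<double>(agent["blip_dur_ms"]);
  double lose_shift = as<double>(agent["lose_shift_prob"]);

  std::vector<double> wcum(dir_weights.size());
  double acc = 0;
  for (int i = 0; i < dir_weights.size(); ++i) { acc += dir_weights[i]; wcum[i] = acc; }

  // ---- engine state ----
  Phase phase = PH_ITI;
  int trial = 0;
  double threshold = amp_threshold;
  double cross_t = -1, cue_t = -1, iti_end = -1, timeout_end = -1;
  int pending_iti = 0;
  int rewards = 0, punishments = 0;
  double p1 = p0[0], p2 = p0[1];
  int block_count = 0;
  bool started = false;

  // ---- agent state ----
  bool active = false;
  Plan plan;
  double plan_t0 = 0;
  double sched_t = -1, anticip_t = -1;
  bool in_timeout = false;
  bool in_trial = false;
  int last_k = 0;             // 1-based when set
  bool have_history = false, last_win = false;
  bool crossed_this = false, rewarded_this = false;

  // ---- output ----
  NumericVector ts(n_ticks), xs(n_ticks), ys(n_ticks);
  std::vector<EventRec> events;
  events.reserve(4096);
  std::vector<int> pending;       // event kinds of the previous tick

  double reach_prob = reach_rate * tick / 1000.0;
  double blip_prob = blip_rate * tick / 1000.0;

  auto unif_ms = [&](int lo, int hi) -> int {
    int n_vals = (hi - lo) / tick + 1;
    return lo + tick * (int)std::floor(unif_rand() * n_vals);
  };
  auto rnorm1 = [&](double m, double s) { return m + s * norm_rand(); };

  auto draw_main_plan = [&](bool bandit) {
    double ang;
    if (bandit) {
      int k;
      if (!have_history) k = (unif_rand() < 0.5) ? 1 : 2;
      else if (last_win) k = last_k;
      else if (unif_rand() < lose_shift) k = 3 - last_k;
      else k = last_k;
      last_k = k;
      ang = centers[k - 1];
    } else {
      double u = unif_rand();
      int k = 0;
      while (k < (int)wcum.size() - 1 && u >= wcum[k]) ++k;
      ang = dir_angles[k];
    }
    if (angular_sd > 0) ang += rnorm1(0, angular_sd);
    double A = rnorm1(amp_mean, amp_sd);
    if (A < 0.1) A = 0.1;
    double half = std::nearbyint(rnorm1(dur_mean, dur_sd) / 2.0 / tick);
    if (half < 25) half = 25;
    double D = 2.0 * half * tick;
    plan = Plan();
    plan.direction = ang; plan.amplitude = A; plan.duration = D;
    if (unif_rand() < revup_prob) {
      double rr = std::nearbyint(0.2 * D / tick);
      if (rr < 1) rr = 1;
      plan.has_revup = true;
      plan.revup_amp = revup_frac * A;
      plan.revup_dur = 2.0 * rr * tick;
    }
  };

  auto draw_blip_plan_cpp = [&]() {
    double ang = -PI + 2.0 * PI * unif_rand();
    double hh = std::nearbyint(blip_dur / 2.0 / tick);
    if (hh < 1) hh = 1;
    plan = Plan();
    plan.direction = ang; plan.amplitude = blip_amp;
    plan.duration = 2.0 * hh * tick;
  };

  auto vao_thr = [&](int tr) -> double {
    double v = amp_threshold;
    for (int i = 0; i < vao_trials.size(); ++i)
      if (vao_trials[i] <= tr) v = vao_thresholds[i];
    return v;
  };

  auto emit = [&](double t, int kind, std::string payload) {
    events.push_back(EventRec{t, kind, trial, std::move(payload)});
    pending.push_back(kind);
  };

  auto start_trial = [&](double t) {
    ++trial;
    cross_t = -1;
    if (variant == V_VAO) threshold = vao_thr(trial);
    if (variant == V_REACTION_TIME) {
      int cd = unif_ms(cue_lo, cue_hi);
      cue_t = t + cd;
      phase = PH_PRE_CUE;
      emit(t, EV_TRIAL_START, fmt("trial=%d&cue_delay=%d", trial, cd));
    } else {
      phase = PH_ARMED;
      emit(t, EV_TRIAL_START, fmt("trial=%d", trial));
    }
  };

  auto enter_iti = [&](double t, int iti) {
    phase = PH_ITI;
    iti_end = t + iti;
    emit(t, EV_ITI_START, fmt("trial=%d&iti=%d", trial, iti));
  };

  for (int i = 0; i < n_ticks; ++i) {
    double t = (double)i * tick;

    // ---- agent: process last tick's events, then emit the sample ----
    for (int kind : pending) {
      switch (kind) {
      case EV_TRIAL_START:
        in_timeout = false;
        in_trial = true;
        if (variant == V_REACTION_TIME) {
          sched_t = -1;
          if (unif_rand() < anticip_prob) {
            double lat = anticip_range[0] +
              unif_rand() * (anticip_range[1] - anticip_range[0]);
            anticip_t = t + std::nearbyint(lat / tick) * tick;
          } else anticip_t = -1;
        }
        break;
      case EV_CUE_ON: {
        double lat = rnorm1(rt_mean, rt_sd);
        double d = std::nearbyint(lat / tick) * tick;
        if (d < tick) d = tick;
        sched_t = t + d;
        anticip_t = -1;
        break;
      }
      case EV_PUNISHMENT_START:
        in_timeout = true; in_trial = false; sched_t = -1; anticip_t = -1;
        break;
      case EV_THRESHOLD_CROSS: crossed_this = true; in_trial = false; break;
      case EV_REWARD: rewarded_this = true; break;
      case EV_ITI_START:
        in_timeout = false;
        in_trial = false;
        if (crossed_this) { have_history = true; last_win = rewarded_this; }
        crossed_this = false; rewarded_this = false;
        break;
      default: break;
      }
    }
    pending.clear();

    if (active && t - plan_t0 >= plan.total()) active = false;

    if (!active && !in_timeout) {
      if (variant == V_REACTION_TIME) {
        if ((sched_t >= 0 && t >= sched_t) ||
            (anticip_t >= 0 && t >= anticip_t)) {
          draw_main_plan(false);
          plan_t0 = t; active = true; sched_t = -1; anticip_t = -1;
        } else if (unif_rand() < blip_prob) {
          draw_blip_plan_cpp(); plan_t0 = t; active = true;
        }
      } else {
        // bandit choices wait for the armed window so the previous
        // trial's outcome is known (matches the R reference agent)
        bool may_reach = (variant != V_BANDIT) || in_trial;
        if (may_reach && unif_rand() < reach_prob) {
          draw_main_plan(variant == V_BANDIT);
          plan_t0 = t; active = true;
        } else if (unif_rand() < blip_prob) {
          draw_blip_plan_cpp(); plan_t0 = t; active = true;
        }
      }
    }

    double r = active ? plan.offset(t - plan_t0) : 0.0;
    double x = x0 + std::cos(plan.direction) * r;
    double y = y0 + std::sin(plan.direction) * r;
    if (jitter_sd > 0) {
      x += rnorm1(0, jitter_sd);
      y += rnorm1(0, jitter_sd);
    }
    ts[i] = t; xs[i] = x; ys[i] = y;

    // ---- engine: scheduled transitions, then threshold test ----
    if (!started) {
      started = true;
      start_trial(t);
    } else if (phase == PH_REWARD_PENDING && t == cross_t + reward_delay) {
      ++rewards;
      if (variant == V_BANDIT) {
        ++block_count;
        if (block_count >= min_block) {
          double u = unif_rand();
          emit(t, EV_REWARD, fmt("trial=%d&switch_u=%.17g", trial, u));
          if (u < switch_prob) {
            double tmp = p1; p1 = p2; p2 = tmp;
            block_count = 0;
            emit(t, EV_BLOCK_SWITCH,
                 fmt("trial=%d&p1=%.17g&p2=%.17g", trial, p1, p2));
          }
        } else {
          emit(t, EV_REWARD, fmt("trial=%d", trial));
        }
      } else {
        emit(t, EV_REWARD, fmt("trial=%d", trial));
      }
      enter_iti(t, iti_ms);
    } else if (phase == PH_ITI && t == iti_end) {
      start_trial(t);
    } else if (phase == PH_TIMEOUT && t == timeout_end) {
      enter_iti(t, pending_iti);
    } else if (phase == PH_PRE_CUE && t == cue_t) {
      phase = PH_ARMED;
      emit(t, EV_CUE_ON, fmt("trial=%d", trial));
    }

    double dx = x - x0, dy = y - y0;
    double disp = std::sqrt(dx * dx + dy * dy);
    if (phase == PH_ARMED && disp >= threshold) {
      if (variant == V_BANDIT) {
        int sect = -1;
        double ang = std::atan2(dy, dx);
        for (int s = 0; s < 2; ++s) {
          double d = wrap_angle(ang - centers[s]);
          if (d >= -halfwidth && d < halfwidth) { sect = s; break; }
        }
        double u = unif_rand();
        if (sect < 0) {
          emit(t, EV_THRESHOLD_CROSS,
               fmt("trial=%d&threshold=%.17g&direction=none&u=%.17g",
                   trial, threshold, u));
          ++block_count;
          enter_iti(t, iti_ms);
        } else {
          double pr = (sect == 0) ? p1 : p2;
          emit(t, EV_THRESHOLD_CROSS,
               fmt("trial=%d&threshold=%.17g&direction=%s&p=%.17g&u=%.17g",
                   trial, threshold,
                   as<std::string>(labels[sect]).c_str(), pr, u));
          if (u < pr) {
            cross_t = t;
            phase = PH_REWARD_PENDING;
          } else {
            ++block_count;
            enter_iti(t, iti_ms);
          }
        }
      } else {
        emit(t, EV_THRESHOLD_CROSS,
             fmt("trial=%d&threshold=%.17g", trial, threshold));
        cross_t = t;
        phase = PH_REWARD_PENDING;
      }
    } else if (phase == PH_PRE_CUE && disp >= threshold && punishment) {
      int niti = unif_ms(piti_lo, piti_hi);
      emit(t, EV_PUNISHMENT_START,
           fmt("trial=%d&timeout=%d&next_iti=%d", trial, timeout_ms, niti));
      ++punishments;
      phase = PH_TIMEOUT;
      timeout_end = t + timeout_ms;
      pending_iti = niti;
    }
  }

  int m = events.size();
  NumericVector ev_t(m);
  CharacterVector ev_kind(m), ev_payload(m);
  IntegerVector ev_trial(m);
  for (int i = 0; i < m; ++i) {
    ev_t[i] = events[i].t;
    ev_kind[i] = EV_NAMES[events[i].kind];
    ev_trial[i] = events[i].trial;
    ev_payload[i] = events[i].payload;
  }
  return List::create(_["t"] = ts, _["x"] = xs, _["y"] = ys,
                      _["ev_t"] = ev_t, _["ev_kind"] = ev_kind,
                      _["ev_trial"] = ev_trial, _["ev_payload"] = ev_payload,
                      _["rewards"] = rewards, _["punishments"] = punishments);
}
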