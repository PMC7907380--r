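// Core herd-dynamics loop: correlated random walk with three-zone social
// interactions, move/rest switching, suitability-coupled speeds, and the
// behavioral-response state machine (flight / regroup) with planted labels.
// Uses R's RNG; the draw order per step (turn, speed, switch) is fixed and
// independent of behavioral state, so an intruder that never triggers any
// animal leaves the trajectory stream bit-identical.
#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap_pi(double a) {
  // avoids fmod: inputs are always within a few turns of (-pi, pi]
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a <= -M_PI) a += 2.0 * M_PI;
  return a;
}

// [[Rcpp::export]]
List herd_sim_core(int T, int n,
                   NumericVector x0, NumericVector y0, NumericVector h0,
                   LogicalVector moving0,
                   IntegerVector herd,
                   NumericVector lmu, NumericVector lsd, NumericVector p_move,
                   NumericVector m_speed,
                   NumericMatrix suit,
                   IntegerVector suit_col,
                   double origin_x, double origin_y, double cell_m, int ncell,
                   double rep_r, double ali_r, double rep_w, double ali_w,
                   double coh_w, double pers_w,
                   double turn_sd, double coupling,
                   double xmin, double xmax, double ymin, double ymax,
                   bool has_intr, NumericVector ix, NumericVector iy,
                   LogicalVector iactive, double detect_r,
                   NumericMatrix resp_dur,
                   IntegerMatrix resp_int,
                   bool eff_active, double eff_speed_mult, double eff_turn_sd_flight,
                   double eff_align_mult, double eff_odba_mult,
                   double eff_flee_w, double eff_regroup_coh_mult,
                   double regroup_dur_s,
                   NumericMatrix X, NumericMatrix Y, NumericMatrix H,
                   NumericMatrix S, NumericMatrix OD,
                   IntegerMatrix LBL, IntegerMatrix INT) {
  std::vector<double> x(n), y(n), h(n);
  std::vector<int> mode(n, 0), inten(n, 0), ndraw(n, 0);
  std::vector<double> mode_end(n, 0.0);
  std::vector<bool> moving(n);
  for (int a = 0; a < n; ++a) {
    x[a] = x0[a]; y[a] = y0[a]; h[a] = h0[a]; moving[a] = moving0[a];
  }
  int nherd = 0;
  for (int a = 0; a < n; ++a) nherd = std::max(nherd, herd[a]);
  std::vector<std::vector<int>> members(nherd);
  for (int a = 0; a < n; ++a) members[herd[a] - 1].push_back(a);
  long reflections = 0;
  const double wI_tab[3] = {0.5, 0.75, 1.0};

  for (int t = 0; t < T; ++t) {
    NumericVector z_turn = Rcpp::rnorm(n);
    NumericVector z_speed = Rcpp::rnorm(n);
    NumericVector u_switch = Rcpp::runif(n);
    for (int a = 0; a < n; ++a)
      if (u_switch[a] > 0.9967) moving[a] = !moving[a];

    if (has_intr) {
      double ixx = ix[t], iyy = iy[t];
      bool act = iactive[t];
      for (int a = 0; a < n; ++a) {
        double d = std::sqrt((ixx - x[a])*(ixx - x[a]) + (iyy - y[a])*(iyy - y[a]));
        if (act && d < detect_r && mode[a] != 1) {
          ndraw[a] = (ndraw[a] % 50);
          mode[a] = 1;
          mode_end[a] = t + resp_dur(ndraw[a], a);
          inten[a] = resp_int(ndraw[a], a);
          ndraw[a]++;
        }
        if (mode[a] == 1 && t >= mode_end[a]) {
          mode[a] = 2; mode_end[a] = t + regroup_dur_s;
        } else if (mode[a] == 2 && t >= mode_end[a]) {
          mode[a] = 0;
        }
      }
    }

    // social forces
    std::vector<double> vx(n), vy(n);
    for (int a = 0; a < n; ++a) {
      double pw = (mode[a] == 1 && eff_active) ? 2.0 * pers_w : pers_w;
      vx[a] = pw * std::cos(h[a]);
      vy[a] = pw * std::sin(h[a]);
    }
    for (int hd = 0; hd < nherd; ++hd) {
      const std::vector<int>& idx = members[hd];
      int nh = idx.size();
      double gx = 0, gy = 0;
      for (int i = 0; i < nh; ++i) { gx += x[idx[i]]; gy += y[idx[i]]; }
      gx /= nh; gy /= nh;
      for (int i = 0; i < nh; ++i) {
        int a = idx[i];
        double rx = 0, ry = 0, ax = 0, ay = 0;
        int nnb = 0;
        for (int j = 0; j < nh; ++j) {
          if (j == i) continue;
          int b = idx[j];
          double dx = x[a] - x[b], dy = y[a] - y[b];
          double d2 = dx * dx + dy * dy;
          if (d2 < rep_r * rep_r) {
            double d = std::sqrt(d2) + 1e-9;
            rx += dx / d; ry += dy / d;
          }
          if (d2 < ali_r * ali_r) {
            ax += std::cos(h[b]); ay += std::sin(h[b]);
            nnb++;
          }
        }
        vx[a] += rep_w * rx; vy[a] += rep_w * ry;
        if (nnb > 0) {
          double wa = ali_w * ((mode[a] == 1) ? eff_align_mult : 1.0);
          vx[a] += wa * ax / nnb; vy[a] += wa * ay / nnb;
        }
        double ddx = gx - x[a], ddy = gy - y[a];
        double dd = std::sqrt((ddx)*(ddx) + (ddy)*(ddy)) + 1e-9;
        double wc = coh_w * std::min(dd / 100.0, 1.0) *
          ((mode[a] == 2) ? eff_regroup_coh_mult : 1.0);
        vx[a] += wc * ddx / dd; vy[a] += wc * ddy / dd;
      }
    }
    if (has_intr) {
      double ixx = ix[t], iyy = iy[t];
      for (int a = 0; a < n; ++a) {
        if (mode[a] == 1 && eff_flee_w > 0) {
          double wIa = wI_tab[std::max(inten[a], 1) - 1];
          double axx = x[a] - ixx, ayy = y[a] - iyy;
          double ad = std::sqrt((axx)*(axx) + (ayy)*(ayy)) + 1e-9;
          vx[a] += eff_flee_w * wIa * axx / ad;
          vy[a] += eff_flee_w * wIa * ayy / ad;
        }
      }
    }

    for (int a = 0; a < n; ++a) {
      double wIa = wI_tab[std::max(inten[a], 1) - 1];
      double tsd = (mode[a] == 1) ? turn_sd + (eff_turn_sd_flight - turn_sd) * wIa
                                  : turn_sd;
      h[a] = wrap_pi(std::atan2(vy[a], vx[a]) + tsd * z_turn[a]);

      // suitability lookup
      int ci = (int)std::floor((x[a] - origin_x) / cell_m);
      int cj = (int)std::floor((y[a] - origin_y) / cell_m);
      if (ci < 0) ci = 0; if (ci >= ncell) ci = ncell - 1;
      if (cj < 0) cj = 0; if (cj >= ncell) cj = ncell - 1;
      double su = suit(ci + (size_t)ncell * cj, suit_col[a] - 1);
      double scale = (1.0 - coupling) + coupling * su;
      double sp = std::exp(lmu[a] + lsd[a] * z_speed[a]) * scale;
      bool in_flight = (mode[a] == 1);
      bool resting = !moving[a] && !(in_flight && eff_active);
      if (resting) sp *= 0.02;
      if (in_flight) sp *= 1.0 + (eff_speed_mult - 1.0) * wIa;
      if (mode[a] == 2 && eff_active) sp = std::max(sp, 0.3 * m_speed[a]);

      x[a] += sp * std::cos(h[a]);
      y[a] += sp * std::sin(h[a]);
      bool clamped = in_flight && eff_active;
      if (x[a] < xmin || x[a] > xmax) {
        reflections++;
        if (clamped) x[a] = std::min(std::max(x[a], xmin), xmax);
        else {
          if (x[a] < xmin) x[a] = 2 * xmin - x[a];
          else x[a] = 2 * xmax - x[a];
          h[a] = wrap_pi(M_PI - h[a]);
        }
      }
      if (y[a] < ymin || y[a] > ymax) {
        reflections++;
        if (clamped) y[a] = std::min(std::max(y[a], ymin), ymax);
        else {
          if (y[a] < ymin) y[a] = 2 * ymin - y[a];
          else y[a] = 2 * ymax - y[a];
          h[a] = wrap_pi(-h[a]);
        }
      }

      double odba_gain = in_flight ? eff_odba_mult / std::max(eff_speed_mult, 1e-9)
                                   : 1.0;
      X(t, a) = x[a]; Y(t, a) = y[a]; H(t, a) = h[a]; S(t, a) = sp;
      OD(t, a) = 0.05 + 0.4 * sp * odba_gain;
      LBL(t, a) = mode[a];
      INT(t, a) = (mode[a] > 0) ? inten[a] : 0;
    }
  }
  return List::create(Named("reflections") = (double)reflections);
}
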