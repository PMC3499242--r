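#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Saturating benefit B(x) = B0 (1 - exp(-B1 x)) and linear cost C(x) = K x.
// All iterated-game loops live here; R wrappers validate inputs.

static inline double benefit_c(double x, double B0, double B1) {
  return B0 * (1.0 - std::exp(-B1 * x));
}

// One full T-round interaction between X = (oX, rX) and Y = (oY, rY).
// Round 1 invests the offer; later rounds follow the linear reactive rule
// I(t) = max(0, offer + reward * P(t-1)) with P the previous round's own
// net payoff. Accumulates both totals.
static inline void play_totals(double oX, double rX, double oY, double rY,
                               double B0, double B1, double K, int T,
                               double &totX, double &totY) {
  double iX = oX, iY = oY, pX = 0.0, pY = 0.0;
  totX = 0.0; totY = 0.0;
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      iX = oX + rX * pX; if (iX < 0.0) iX = 0.0;
      iY = oY + rY * pY; if (iY < 0.0) iY = 0.0;
    }
    pX = benefit_c(iY, B0, B1) - K * iX;
    pY = benefit_c(iX, B0, B1) - K * iY;
    totX += pX; totY += pY;
  }
}

// [[Rcpp::export]]
List play_interaction_cpp(NumericVector sA, NumericVector sB,
                          double B0, double B1, double K, int T) {
  NumericVector invA(T), invB(T), payA(T), payB(T);
  double iA = sA[0], iB = sB[0], pA = 0.0, pB = 0.0;
  double totA = 0.0, totB = 0.0;
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      iA = sA[0] + sA[1] * pA; if (iA < 0.0) iA = 0.0;
      iB = sB[0] + sB[1] * pB; if (iB < 0.0) iB = 0.0;
    }
    pA = benefit_c(iB, B0, B1) - K * iA;
    pB = benefit_c(iA, B0, B1) - K * iB;
    invA[t] = iA; invB[t] = iB; payA[t] = pA; payB[t] = pB;
    totA += pA; totB += pB;
  }
  return List::create(_["investments_A"] = invA, _["investments_B"] = invB,
                      _["payoffs_A"] = payA, _["payoffs_B"] = payB,
                      _["total_A"] = totA, _["total_B"] = totB);
}

// [[Rcpp::export]]
NumericVector total_payoffs_cpp(NumericVector sA, NumericVector sB,
                                double B0, double B1, double K, int T) {
  double tA, tB;
  play_totals(sA[0], sA[1], sB[0], sB[1], B0, B1, K, T, tA, tB);
  return NumericVector::create(tA, tB);
}

// Grid argmax of the responder's total payoff against a fixed opponent.
// Ties break toward the smaller offer, then the smaller reward, which the
// ascending scan order guarantees with a strict ">" test.
// [[Rcpp::export]]
NumericVector best_response_cpp(NumericVector opponent,
                                double B0, double B1, double K, int T,
                                NumericVector offers, NumericVector rewards) {
  const double oOpp = opponent[0], rOpp = opponent[1];
  double best = R_NegInf;
  double bo = offers[0], br = rewards[0];
  int bi = 0, bj = 0;
  double tX, tY;
  for (int i = 0; i < offers.size(); ++i) {
    for (int j = 0; j < rewards.size(); ++j) {
      play_totals(offers[i], rewards[j], oOpp, rOpp, B0, B1, K, T, tX, tY);
      if (tX > best) {
        best = tX; bo = offers[i]; br = rewards[j]; bi = i; bj = j;
      }
    }
  }
  return NumericVector::create(_["offer"] = bo, _["reward"] = br,
                               _["payoff"] = best,
                               _["i_offer"] = bi + 1, _["i_reward"] = bj + 1);
}

// Summed total payoff of a mutant (focal guild) against a set of partners.
// [[Rcpp::export]]
double payoff_vs_many_cpp(NumericVector mutant, NumericMatrix partners,
                          double B0, double B1, double K, int T) {
  double sum = 0.0, tX, tY;
  for (int i = 0; i < partners.nrow(); ++i) {
    play_totals(mutant[0], mutant[1], partners(i, 0), partners(i, 1),
                B0, B1, K, T, tX, tY);
    sum += tX;
  }
  return sum;
}

// Finite-difference selection gradient of the focal strategy's (summed)
// payoff against a partner collection; central differences, one-sided when
// a trait sits within h of the zero boundary.
// [[Rcpp::export]]
NumericVector sel_gradient_cpp(NumericVector focal, NumericMatrix partners,
                               double B0, double B1, double K, int T,
                               double h) {
  NumericVector g(2);
  for (int d = 0; d < 2; ++d) {
    NumericVector up = clone(focal), dn = clone(focal);
    if (focal[d] < h) {          // boundary: forward difference
      up[d] = focal[d] + h;
      double fu = payoff_vs_many_cpp(up, partners, B0, B1, K, T);
      double f0 = payoff_vs_many_cpp(focal, partners, B0, B1, K, T);
      g[d] = (fu - f0) / h;
    } else {
      up[d] = focal[d] + h; dn[d] = focal[d] - h;
      double fu = payoff_vs_many_cpp(up, partners, B0, B1, K, T);
      double fd = payoff_vs_many_cpp(dn, partners, B0, B1, K, T);
      g[d] = (fu - fd) / (2.0 * h);
    }
  }
  return g;
}

// Explicit Euler co-integration of both guilds' traits along their
// monomorphic selection gradients; traits clamped to [0, cap].
// [[Rcpp::export]]
List gradient_flow_cpp(NumericVector startA, NumericVector startB,
                       double B0, double B1, double K, int T,
                       double h, double step, int nsteps, double cap) {
  NumericMatrix traits(nsteps + 1, 4);
  NumericMatrix grads(nsteps + 1, 4);
  NumericVector a = clone(startA), b = clone(startB);
  NumericMatrix pa(1, 2), pb(1, 2);
  int done = nsteps;
  for (int s = 0; s <= nsteps; ++s) {
    traits(s, 0) = a[0]; traits(s, 1) = a[1];
    traits(s, 2) = b[0]; traits(s, 3) = b[1];
    pa(0, 0) = a[0]; pa(0, 1) = a[1];
    pb(0, 0) = b[0]; pb(0, 1) = b[1];
    NumericVector gA = sel_gradient_cpp(a, pb, B0, B1, K, T, h);
    NumericVector gB = sel_gradient_cpp(b, pa, B0, B1, K, T, h);
    grads(s, 0) = gA[0]; grads(s, 1) = gA[1];
    grads(s, 2) = gB[0]; grads(s, 3) = gB[1];
    if (s == nsteps) break;
    a[0] += step * gA[0]; a[1] += step * gA[1];
    b[0] += step * gB[0]; b[1] += step * gB[1];
    for (int d = 0; d < 2; ++d) {
      if (a[d] < 0.0) a[d] = 0.0; if (a[d] > cap) a[d] = cap;
      if (b[d] < 0.0) b[d] = 0.0; if (b[d] > cap) b[d] = cap;
    }
    // absorbed at the no-investment corner with downhill gradients: stop
    if (a[0] < 1e-12 && a[1] < 1e-12 && b[0] < 1e-12 && b[1] < 1e-12 &&
        gA[0] <= 0.0 && gB[0] <= 0.0) { done = s + 1; break; }
  }
  return List::create(_["traits"] = traits, _["grads"] = grads,
                      _["steps"] = done);
}

// ---------------------------------------------------------------------------
// Individual-based model
// ---------------------------------------------------------------------------

static inline int unif_index(int n) {
  int i = (int)(unif_rand() * n);
  return (i >= n) ? n - 1 : i;
}

static inline double mutate_trait(double v, double mu, int scheme,
                                  double sigma, double cv) {
  if (mu > 0.0 && unif_rand() < mu) {
    double sd = (scheme == 0) ? sigma : cv * v;
    if (sd > 0.0) {
      v += norm_rand() * sd;
      if (v < 0.0) v = 0.0;    // traits are non-negative
    }
  }
  return v;
}

// best-takes-over among contender indices; ties broken uniformly
static inline int bto_winner(const std::vector<int> &cont,
                             const std::vector<double> &pay) {
  double best = R_NegInf;
  for (size_t i = 0; i < cont.size(); ++i)
    if (pay[cont[i]] > best) best = pay[cont[i]];
  int nties = 0;
  for (size_t i = 0; i < cont.size(); ++i)
    if (pay[cont[i]] == best) ++nties;
  int pick = unif_index(nties);
  for (size_t i = 0; i < cont.size(); ++i) {
    if (pay[cont[i]] == best) {
      if (pick == 0) return cont[i];
      --pick;
    }
  }
  return cont[0]; // unreachable
}

static inline double fermi(double dpay, double Ksel) {
  return 1.0 / (1.0 + std::exp(-dpay / Ksel));
}

// Moore-8 neighborhood on a W x W torus, row-major index i = r*W + c
static void moore_neighbors(int W, std::vector<int> &nb) {
  int n = W * W;
  nb.resize(8 * n);
  for (int r = 0; r < W; ++r) {
    for (int c = 0; c < W; ++c) {
      int i = r * W + c, q = 0;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int rr = (r + dr + W) % W, cc = (c + dc + W) % W;
          nb[8 * i + q] = rr * W + cc;
          ++q;
        }
      }
    }
  }
}

// Full simulation run. Strategy state is held in flat arrays
// (offer, reward per guild); payoffs are cached per individual and only
// refreshed as the scheduling rule prescribes.
//
// structure: 0 = lattice (n = W*W, matched-site partners),
//            1 = well-mixed (random partner per evaluation)
// scheme:    0 = constant sigma, 1 = constant CV
// rule:      0 = best-takes-over, 1 = pairwise comparison (Fermi)
// sched:     0 = asynchronous, 1 = synchronous
// refresh:   0 = focal pair only, 1 = focal pair + competitors
// [[Rcpp::export]]
List ibm_run_cpp(NumericMatrix initA, NumericMatrix initB,
                 int structure, int W, int G,
                 double B0, double B1, double K, int T,
                 double mu, int scheme, double sigma, double cv,
                 int rule, double Ksel, int k, int sched, int refresh,
                 int snapshot_every) {
  const int n = initA.nrow();
  std::vector<double> oA(n), rA(n), oB(n), rB(n), payA(n, 0.0), payB(n, 0.0);
  for (int i = 0; i < n; ++i) {
    oA[i] = initA(i, 0); rA[i] = initA(i, 1);
    oB[i] = initB(i, 0); rB[i] = initB(i, 1);
  }
  std::vector<int> nb;
  if (structure == 0) moore_neighbors(W, nb);

  NumericMatrix summary(G, 10);
  List snapshots;
  std::vector<int> cont;
  std::vector<double> nOA(n), nRA(n), nOB(n), nRB(n);
  double tX, tY;

  // initial payoff evaluation against initial partners
  for (int i = 0; i < n; ++i) {
    int j = (structure == 0) ? i : unif_index(n);
    play_totals(oA[i], rA[i], oB[j], rB[j], B0, B1, K, T, tX, tY);
    payA[i] = tX;
    if (structure == 0) payB[i] = tY;
  }
  if (structure == 1) {
    for (int i = 0; i < n; ++i) {
      int j = unif_index(n);
      play_totals(oB[i], rB[i], oA[j], rA[j], B0, B1, K, T, tX, tY);
      payB[i] = tX;
    }
  }

  for (int g = 0; g < G; ++g) {
    if (sched == 1) {
      // ---- synchronous generation ----
      // 1) evaluate all payoffs on the frozen community
      for (int i = 0; i < n; ++i) {
        int j = (structure == 0) ? i : unif_index(n);
        play_totals(oA[i], rA[i], oB[j], rB[j], B0, B1, K, T, tX, tY);
        payA[i] = tX;
        if (structure == 0) payB[i] = tY;
      }
      if (structure == 1) {
        for (int i = 0; i < n; ++i) {
          int j = unif_index(n);
          play_totals(oB[i], rB[i], oA[j], rA[j], B0, B1, K, T, tX, tY);
          payB[i] = tX;
        }
      }
      // 2) competition, written simultaneously
      for (int i = 0; i < n; ++i) {
        int winA, winB;
        if (rule == 0) {
          cont.clear(); cont.push_back(i);
          if (structure == 0) {
            for (int q = 0; q < 8; ++q) cont.push_back(nb[8 * i + q]);
          } else {
            for (int q = 0; q < k; ++q) cont.push_back(unif_index(n));
          }
          winA = bto_winner(cont, payA);
          cont.clear(); cont.push_back(i);
          if (structure == 0) {
            for (int q = 0; q < 8; ++q) cont.push_back(nb[8 * i + q]);
          } else {
            for (int q = 0; q < k; ++q) cont.push_back(unif_index(n));
          }
          winB = bto_winner(cont, payB);
        } else {
          int cA = (structure == 0) ? nb[8 * i + unif_index(8)] : unif_index(n);
          winA = (unif_rand() < fermi(payA[cA] - payA[i], Ksel)) ? cA : i;
          int cB = (structure == 0) ? nb[8 * i + unif_index(8)] : unif_index(n);
          winB = (unif_rand() < fermi(payB[cB] - payB[i], Ksel)) ? cB : i;
        }
        nOA[i] = oA[winA]; nRA[i] = rA[winA];
        nOB[i] = oB[winB]; nRB[i] = rB[winB];
      }
      // 3) mutation on every written strategy
      for (int i = 0; i < n; ++i) {
        oA[i] = mutate_trait(nOA[i], mu, scheme, sigma, cv);
        rA[i] = mutate_trait(nRA[i], mu, scheme, sigma, cv);
        oB[i] = mutate_trait(nOB[i], mu, scheme, sigma, cv);
        rB[i] = mutate_trait(nRB[i], mu, scheme, sigma, cv);
      }
    } else {
      // ---- asynchronous generation: n single-site updates ----
      for (int u = 0; u < n; ++u) {
        if (structure == 0) {
          int i = unif_index(n);
          play_totals(oA[i], rA[i], oB[i], rB[i], B0, B1, K, T, tX, tY);
          payA[i] = tX; payB[i] = tY;
          if (refresh == 1) {
            for (int q = 0; q < 8; ++q) {
              int j = nb[8 * i + q];
              play_totals(oA[j], rA[j], oB[j], rB[j], B0, B1, K, T, tX, tY);
              payA[j] = tX; payB[j] = tY;
            }
          }
          int winA, winB;
          if (rule == 0) {
            cont.clear(); cont.push_back(i);
            for (int q = 0; q < 8; ++q) cont.push_back(nb[8 * i + q]);
            winA = bto_winner(cont, payA);
            winB = bto_winner(cont, payB);
          } else {
            int cA = nb[8 * i + unif_index(8)];
            winA = (unif_rand() < fermi(payA[cA] - payA[i], Ksel)) ? cA : i;
            int cB = nb[8 * i + unif_index(8)];
            winB = (unif_rand() < fermi(payB[cB] - payB[i], Ksel)) ? cB : i;
          }
          oA[i] = mutate_trait(oA[winA], mu, scheme, sigma, cv);
          rA[i] = mutate_trait(rA[winA], mu, scheme, sigma, cv);
          oB[i] = mutate_trait(oB[winB], mu, scheme, sigma, cv);
          rB[i] = mutate_trait(rB[winB], mu, scheme, sigma, cv);
        } else {
          // well-mixed: draw an interacting A-B pair
          int a = unif_index(n), b = unif_index(n);
          play_totals(oA[a], rA[a], oB[b], rB[b], B0, B1, K, T, tX, tY);
          payA[a] = tX; payB[b] = tY;
          int winA, winB;
          if (rule == 0) {
            cont.clear(); cont.push_back(a);
            for (int q = 0; q < k; ++q) {
              int c = unif_index(n);
              if (refresh == 1) {
                int pb = unif_index(n);
                play_totals(oA[c], rA[c], oB[pb], rB[pb], B0, B1, K, T, tX, tY);
                payA[c] = tX;
              }
              cont.push_back(c);
            }
            winA = bto_winner(cont, payA);
            cont.clear(); cont.push_back(b);
            for (int q = 0; q < k; ++q) {
              int c = unif_index(n);
              if (refresh == 1) {
                int pa = unif_index(n);
                play_totals(oB[c], rB[c], oA[pa], rA[pa], B0, B1, K, T, tX, tY);
                payB[c] = tX;
              }
              cont.push_back(c);
            }
            winB = bto_winner(cont, payB);
          } else {
            int cA = unif_index(n);
            if (refresh == 1) {
              int pb = unif_index(n);
              play_totals(oA[cA], rA[cA], oB[pb], rB[pb], B0, B1, K, T, tX, tY);
              payA[cA] = tX;
            }
            winA = (unif_rand() < fermi(payA[cA] - payA[a], Ksel)) ? cA : a;
            int cB = unif_index(n);
            if (refresh == 1) {
              int pa = unif_index(n);
              play_totals(oB[cB], rB[cB], oA[pa], rA[pa], B0, B1, K, T, tX, tY);
              payB[cB] = tX;
            }
            winB = (unif_rand() < fermi(payB[cB] - payB[b], Ksel)) ? cB : b;
          }
          oA[a] = mutate_trait(oA[winA], mu, scheme, sigma, cv);
          rA[a] = mutate_trait(rA[winA], mu, scheme, sigma, cv);
          oB[b] = mutate_trait(oB[winB], mu, scheme, sigma, cv);
          rB[b] = mutate_trait(rB[winB], mu, scheme, sigma, cv);
        }
      }
    }

    // per-generation summary: trait means/variances and mean cached payoffs
    double mo = 0, mr = 0, vo = 0, vr = 0, mp = 0;
    for (int i = 0; i < n; ++i) { mo += oA[i]; mr += rA[i]; mp += payA[i]; }
    mo /= n; mr /= n; mp /= n;
    for (int i = 0; i < n; ++i) {
      vo += (oA[i] - mo) * (oA[i] - mo);
      vr += (rA[i] - mr) * (rA[i] - mr);
    }
    summary(g, 0) = mo; summary(g, 1) = vo / n;
    summary(g, 2) = mr; summary(g, 3) = vr / n;
    summary(g, 8) = mp;
    mo = 0; mr = 0; vo = 0; vr = 0; mp = 0;
    for (int i = 0; i < n; ++i) { mo += oB[i]; mr += rB[i]; mp += payB[i]; }
    mo /= n; mr /= n; mp /= n;
    for (int i = 0; i < n; ++i) {
      vo += (oB[i] - mo) * (oB[i] - mo);
      vr += (rB[i] - mr) * (rB[i] - mr);
    }
    summary(g, 4) = mo; summary(g, 5) = vo / n;
    summary(g, 6) = mr; summary(g, 7) = vr / n;
    summary(g, 9) = mp;

    if (snapshot_every > 0 && ((g + 1) % snapshot_every == 0)) {
      NumericMatrix sA(n, 2), sB(n, 2);
      NumericVector pA(n), pB(n);
      for (int i = 0; i < n; ++i) {
        sA(i, 0) = oA[i]; sA(i, 1) = rA[i];
        sB(i, 0) = oB[i]; sB(i, 1) = rB[i];
        pA[i] = payA[i]; pB[i] = payB[i];
      }
      snapshots.push_back(List::create(
          _["generation"] = g + 1, _["A"] = sA, _["B"] = sB,
          _["payoff_A"] = pA, _["payoff_B"] = pB));
    }
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix finA(n, 2), finB(n, 2);
  NumericVector fpA(n), fpB(n);
  for (int i = 0; i < n; ++i) {
    finA(i, 0) = oA[i]; finA(i, 1) = rA[i];
    finB(i, 0) = oB[i]; finB(i, 1) = rB[i];
    fpA[i] = payA[i]; fpB[i] = payB[i];
  }
  return List::create(_["summary"] = summary, _["snapshots"] = snapshots,
                      _["final_A"] = finA, _["final_B"] = finB,
                      _["final_payoff_A"] = fpA, _["final_payoff_B"] = fpB);
}
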