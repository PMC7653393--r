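// Compiled kernels for the three single-scale engines and the two
// blending-region couplers.  All randomness comes from R's RNG (unif_rand,
// norm_rand, exp_rand, R::rpois) so that set.seed() in R fully determines
// every simulation path.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Crank-Nicolson finite-volume stepper for d(c)/dt = d/dx( D(x) dc/dx ) + R(c)
// on a cell-centred grid.  faceD holds the diffusivity at the n+1 cell faces;
// the two outer faces must carry 0 (their flux is prescribed via Ja, Jb:
// the value of D*dc/dx at the boundary, so mass enters at rate Jb - Ja).
// Reactions R(c) = k2 - mu*c - k1*c^2 are integrated explicitly and can be
// masked to the first nReactVox cells (nReactVox < 0 means all cells).
// ---------------------------------------------------------------------------
struct CnStepper {
    int n;
    double dx, dt, Ja, Jb;
    double k2, mu, k1;
    int nReact;
    std::vector<double> aW, aE;          // D_{i-1/2}/dx^2, D_{i+1/2}/dx^2
    std::vector<double> sub, dia, sup, rhs, cp, dp;

    CnStepper(const std::vector<double>& q, double dx_, const NumericVector& faceD,
              double Ja_, double Jb_, double k2_, double mu_, double k1_,
              int nReact_, double dt_)
        : n((int)q.size()), dx(dx_), dt(dt_), Ja(Ja_), Jb(Jb_),
          k2(k2_), mu(mu_), k1(k1_), nReact(nReact_ < 0 ? (int)q.size() : nReact_),
          aW(n), aE(n), sub(n), dia(n), sup(n), rhs(n), cp(n), dp(n) {
        if ((int)faceD.size() != n + 1) stop("faceD must have n+1 entries");
        double dx2 = dx * dx;
        for (int i = 0; i < n; ++i) {
            aW[i] = faceD[i] / dx2;
            aE[i] = faceD[i + 1] / dx2;
        }
        double r = dt / 2.0;
        for (int i = 0; i < n; ++i) {
            sub[i] = -r * aW[i];
            dia[i] = 1.0 + r * (aW[i] + aE[i]);
            sup[i] = -r * aE[i];
        }
    }

    void step(std::vector<double>& q) {
        double r = dt / 2.0;
        // rhs = (I + r A) q + dt * boundary-flux
        for (int i = 0; i < n; ++i) {
            double Aq = 0.0;
            if (i > 0)     Aq += aW[i] * (q[i - 1] - q[i]);
            if (i < n - 1) Aq += aE[i] * (q[i + 1] - q[i]);
            rhs[i] = q[i] + r * Aq;
        }
        rhs[0]     += dt * (-Ja / dx);
        rhs[n - 1] += dt * ( Jb / dx);
        // Thomas algorithm for (I - r A) q_new = rhs
        cp[0] = sup[0] / dia[0];
        dp[0] = rhs[0] / dia[0];
        for (int i = 1; i < n; ++i) {
            double m = dia[i] - sub[i] * cp[i - 1];
            cp[i] = sup[i] / m;
            dp[i] = (rhs[i] - sub[i] * dp[i - 1]) / m;
        }
        q[n - 1] = dp[n - 1];
        for (int i = n - 2; i >= 0; --i) q[i] = dp[i] - cp[i] * q[i + 1];
        // explicit reaction update on the (possibly masked) cells
        if (k2 != 0.0 || mu != 0.0 || k1 != 0.0) {
            for (int i = 0; i < nReact; ++i)
                q[i] += dt * (k2 - mu * q[i] - k1 * q[i] * q[i]);
        }
    }
};

// [[Rcpp::export]]
NumericVector cpp_pde_run(NumericVector q0, double dx, NumericVector faceD,
                          double Ja, double Jb,
                          double k2, double mu, double k1, int nReactVox,
                          double dt, int nsteps) {
    std::vector<double> q(q0.begin(), q0.end());
    CnStepper st(q, dx, faceD, Ja, Jb, k2, mu, k1, nReactVox, dt);
    for (int s = 0; s < nsteps; ++s) st.step(q);
    return wrap(q);
}

// ---------------------------------------------------------------------------
// Gillespie direct method on a chain of compartments.
//
// Per-compartment channels: jump left (per-particle rate rateL), jump right
// (rateR), zeroth-order production (propensity k0, already including volume
// and any boundary influx), first-order decay (mu * C) and pair annihilation
// 2A -> 0 (k1 * C * (C-1) / (2 V)).  Counts are stored as doubles because the
// couplers synchronise non-integer mass into blending compartments; all
// propensities floor at zero so transiently negative counts cannot fire.
// ---------------------------------------------------------------------------
struct SsaRegion {
    int n;
    std::vector<double> C, rateL, rateR, V, k0, prop;
    double mu, k1, total;

    SsaRegion(const NumericVector& C0, const NumericVector& rL, const NumericVector& rR,
              const NumericVector& V_, const NumericVector& k0_, double mu_, double k1_)
        : n((int)C0.size()), C(C0.begin(), C0.end()), rateL(rL.begin(), rL.end()),
          rateR(rR.begin(), rR.end()), V(V_.begin(), V_.end()),
          k0(k0_.begin(), k0_.end()), mu(mu_), k1(k1_) {
        prop.resize(n);
        recompute();
    }

    double calc(int i) const {
        double Cp = std::max(C[i], 0.0);
        double a = Cp * (rateL[i] + rateR[i]) + k0[i] + mu * Cp;
        if (k1 > 0.0) a += k1 * std::max(Cp * (Cp - 1.0), 0.0) / (2.0 * V[i]);
        return a;
    }
    void recompute() {
        total = 0.0;
        for (int i = 0; i < n; ++i) { prop[i] = calc(i); total += prop[i]; }
    }
    void refresh(int i) {
        double old = prop[i];
        prop[i] = calc(i);
        total += prop[i] - old;
    }
};

// Coupling policies: invoked after the SSA has updated the counts.
struct NullPolicy {
    void onJump(int, int) {}
    void onReact(int, int) {}
};

template <class Policy>
static void ssa_advance(SsaRegion& R, double t0, double t1, Policy& pol) {
    double t = t0;
    long its = 0;
    while (true) {
        if (R.total <= 0.0) break;
        double tau = exp_rand() / R.total;
        if (t + tau > t1) break;
        t += tau;
        double u = unif_rand() * R.total;
        int i = 0;
        double acc = R.prop[0];
        while (acc < u && i < R.n - 1) acc += R.prop[++i];
        double v = u - (acc - R.prop[i]);   // offset within compartment i
        double Cp = std::max(R.C[i], 0.0);
        double aL = Cp * R.rateL[i];
        double aR = Cp * R.rateR[i];
        double a0 = R.k0[i];
        double a1 = R.mu * Cp;
        if (v < aL && i > 0) {
            R.C[i] -= 1.0; R.C[i - 1] += 1.0;
            pol.onJump(i, i - 1);
            R.refresh(i); R.refresh(i - 1);
        } else if (v < aL + aR && i < R.n - 1) {
            R.C[i] -= 1.0; R.C[i + 1] += 1.0;
            pol.onJump(i, i + 1);
            R.refresh(i); R.refresh(i + 1);
        } else if (v < aL + aR + a0) {
            R.C[i] += 1.0;
            pol.onReact(i, +1);
            R.refresh(i);
        } else if (v < aL + aR + a0 + a1) {
            R.C[i] -= 1.0;
            pol.onReact(i, -1);
            R.refresh(i);
        } else {
            R.C[i] -= 2.0;
            pol.onReact(i, -2);
            R.refresh(i);
        }
        if ((++its & 0x3FFF) == 0) R.recompute();  // control fp drift
    }
}

// [[Rcpp::export]]
NumericVector cpp_ssa_run(NumericVector C0, NumericVector rateL, NumericVector rateR,
                          NumericVector V, NumericVector k0, double mu, double k1,
                          double t0, double t1) {
    SsaRegion R(C0, rateL, rateR, V, k0, mu, k1);
    NullPolicy pol;
    ssa_advance(R, t0, t1, pol);
    return wrap(R.C);
}

// ---------------------------------------------------------------------------
// PDE-compartment coupler (blending on [I1, I2]; PDE on [a, I2] with D1,
// compartments on [I1, b] with D2).  Per window: CN step (reactions masked to
// the pure-PDE voxels), overwrite blending counts from the PDE, run the SSA,
// then mirror the accumulated integer count changes back into the PDE voxels.
// ---------------------------------------------------------------------------
struct PcPolicy {
    int n2;
    std::vector<double> delta;
    PcPolicy(int n2_) : n2(n2_), delta(n2_, 0.0) {}
    void reset() { std::fill(delta.begin(), delta.end(), 0.0); }
    void onJump(int i, int j) {
        if (i < n2) delta[i] -= 1.0;
        if (j < n2) delta[j] += 1.0;
    }
    void onReact(int i, int d) {
        if (i < n2) delta[i] += d;
    }
};

// [[Rcpp::export]]
List cpp_hybrid_pc_run(NumericVector q0, NumericVector C0,
                       double dx, NumericVector faceD1, double Ja,
                       int np, int gamma, int n2,
                       NumericVector rateL, NumericVector rateR,
                       NumericVector V, NumericVector k0, double mu, double k1,
                       double pde_k2, double pde_mu, double pde_k1,
                       double dt, int nwin, bool debug) {
    std::vector<double> q(q0.begin(), q0.end());
    CnStepper st(q, dx, faceD1, Ja, 0.0, pde_k2, pde_mu, pde_k1, np, dt);
    SsaRegion R(C0, rateL, rateR, V, k0, mu, k1);
    PcPolicy pol(n2);
    double t = 0.0;
    for (int w = 0; w < nwin; ++w) {
        st.step(q);                                    // (1) PDE window
        for (int i = 0; i < n2; ++i) {                 // (2) sync PDE -> counts
            double m = 0.0;
            for (int j = 0; j < gamma; ++j) m += q[np + gamma * i + j];
            R.C[i] = m * dx;
        }
        R.recompute();
        pol.reset();
        ssa_advance(R, t, t + dt, pol);                // (3) SSA window
        for (int i = 0; i < n2; ++i) {                 // (4) mirror events -> PDE
            if (pol.delta[i] != 0.0) {
                double add = pol.delta[i] / (gamma * dx);
                for (int j = 0; j < gamma; ++j) q[np + gamma * i + j] += add;
            }
        }
        t += dt;
        if (debug) {
            for (int i = 0; i < n2; ++i) {
                double m = 0.0;
                for (int j = 0; j < gamma; ++j) m += q[np + gamma * i + j];
                m *= dx;
                if (std::fabs(m - R.C[i]) > 1e-6 * (1.0 + std::fabs(R.C[i])))
                    stop("blending consistency violated in PDE-compartment window");
            }
        }
    }
    return List::create(_["q"] = wrap(q), _["C"] = wrap(R.C));
}

// ---------------------------------------------------------------------------
// Compartment-Brownian coupler (compartments on [a, I2] with D1, Brownian
// particles on [I1, b] with D2).  SSA events in the blending compartments are
// mirrored onto the particle set immediately (move by +-h, create uniformly
// in the compartment, or delete a uniformly chosen member); after the SSA the
// particles take one Euler-Maruyama step with reflection, the pure-Brownian
// reactions fire, and the blending counts are reset from the particle
// histogram.
// ---------------------------------------------------------------------------
struct ParticleStore {
    std::vector<double> x, y, z;
    std::vector<char> alive;
    int dim, nAlive;

    void addParticle(double px, double py, double pz) {
        x.push_back(px); y.push_back(py); z.push_back(pz);
        alive.push_back(1);
        ++nAlive;
    }
    void kill(int k) { alive[k] = 0; --nAlive; }
    void compact() {
        int m = 0;
        for (size_t k = 0; k < x.size(); ++k) {
            if (alive[k]) {
                x[m] = x[k]; y[m] = y[k]; z[m] = z[k];
                ++m;
            }
        }
        x.resize(m); y.resize(m); z.resize(m);
        alive.assign(m, 1);
        nAlive = m;
    }
};

struct CbPolicy {
    ParticleStore* P;
    int nc, n2, dim;
    double I1, h, cy, cz;
    std::vector<std::vector<int> > bins;   // particle indices per blending compartment

    CbPolicy(ParticleStore* P_, int nc_, int n2_, int dim_,
             double I1_, double h_, double cy_, double cz_)
        : P(P_), nc(nc_), n2(n2_), dim(dim_), I1(I1_), h(h_), cy(cy_), cz(cz_),
          bins(n2_) {}

    void rebuildBins() {
        for (int i = 0; i < n2; ++i) bins[i].clear();
        double I2 = I1 + n2 * h;
        for (size_t k = 0; k < P->x.size(); ++k) {
            if (!P->alive[k]) continue;
            double px = P->x[k];
            if (px >= I1 && px < I2) {
                int bi = (int)std::floor((px - I1) / h);
                if (bi >= n2) bi = n2 - 1;
                bins[bi].push_back((int)k);
            }
        }
    }
    int pickPos(int bi) {
        int sz = (int)bins[bi].size();
        if (sz == 0)
            stop("blending consistency fault: no Brownian particle available in compartment");
        int p = (int)(unif_rand() * sz);
        if (p >= sz) p = sz - 1;
        return p;
    }
    void removeAt(int bi, int pos) {
        bins[bi][pos] = bins[bi].back();
        bins[bi].pop_back();
    }
    void createIn(int bi) {
        double px = I1 + (bi + unif_rand()) * h;
        double py = dim == 3 ? unif_rand() * cy : 0.0;
        double pz = dim == 3 ? unif_rand() * cz : 0.0;
        P->addParticle(px, py, pz);
        bins[bi].push_back((int)P->x.size() - 1);
    }

    // region indices: 0..nc-1 pure compartments, nc..nc+n2-1 blending
    void onJump(int i, int j) {
        bool ib = i >= nc, jb = j >= nc;
        if (ib && jb) {                       // move a twin particle by +-h
            int bi = i - nc, bj = j - nc;
            int pos = pickPos(bi);
            int k = bins[bi][pos];
            P->x[k] += (j > i) ? h : -h;
            removeAt(bi, pos);
            bins[bj].push_back(k);
        } else if (ib && !jb) {               // left exit: delete a twin
            int bi = i - nc;
            int pos = pickPos(bi);
            P->kill(bins[bi][pos]);
            removeAt(bi, pos);
        } else if (!ib && jb) {               // right entry: create a twin
            createIn(j - nc);
        }
    }
    void onReact(int i, int d) {
        if (i < nc) return;
        int bi = i - nc;
        if (d > 0) {
            for (int r = 0; r < d; ++r) createIn(bi);
        } else {
            for (int r = 0; r < -d; ++r) {
                int pos = pickPos(bi);
                P->kill(bins[bi][pos]);
                removeAt(bi, pos);
            }
        }
    }
};

static inline double d2_of(double x, double I1, double I2, double D) {
    if (x < I1) return 0.0;
    if (x >= I2) return D;
    return D * (x - I1) / (I2 - I1);
}
static inline double d2_slope(double x, double I1, double I2, double D) {
    // one-sided derivative from inside the blending region at the kinks
    if (x >= I1 && x <= I2) return D / (I2 - I1);
    return 0.0;
}
static inline double reflect_into(double v, double lo, double hi, int* tally_lo) {
    while (v < lo || v > hi) {
        if (v < lo) {
            v = 2.0 * lo - v;
            if (tally_lo) ++(*tally_lo);
        }
        if (v > hi) v = 2.0 * hi - v;
    }
    return v;
}

// [[Rcpp::export]]
List cpp_hybrid_cb_run(NumericVector C0, NumericMatrix pos0,
                       int nc, int n2, double I1, double I2, double b,
                       double Dmac, double h, double cy, double cz, int dim,
                       NumericVector rateL, NumericVector rateR,
                       NumericVector V, NumericVector k0, double mu, double k1,
                       double br_k2, double br_mu, double rho, double Plambda,
                       double dt, int nwin, bool debug) {
    SsaRegion R(C0, rateL, rateR, V, k0, mu, k1);
    ParticleStore P;
    P.dim = dim;
    P.nAlive = 0;
    for (int k = 0; k < pos0.nrow(); ++k)
        P.addParticle(pos0(k, 0),
                      dim == 3 ? pos0(k, 1) : 0.0,
                      dim == 3 ? pos0(k, 2) : 0.0);
    CbPolicy pol(&P, nc, n2, dim, I1, h, cy, cz);
    double t = 0.0;
    int reflections = 0;
    double Vb = (b - I2) * (dim == 3 ? cy * cz : 1.0);
    double pkill = br_mu > 0.0 ? 1.0 - std::exp(-br_mu * dt) : 0.0;
    std::vector<int> pure;      // pure-Brownian-region indices, reused
    std::vector<std::pair<int, int> > pairs;

    for (int w = 0; w < nwin; ++w) {
        pol.rebuildBins();
        if (debug) {
            for (int i = 0; i < n2; ++i)
                if (std::fabs((double)pol.bins[i].size() - R.C[nc + i]) > 1e-9)
                    stop("window invariant violated: blending count != particle histogram");
        }
        // (1) SSA on [a, I2] with immediate particle mirroring
        ssa_advance(R, t, t + dt, pol);
        // (2) Euler-Maruyama with drift-corrected spatially varying D2
        for (size_t k = 0; k < P.x.size(); ++k) {
            if (!P.alive[k]) continue;
            double px = P.x[k];
            double Dp = d2_of(px, I1, I2, Dmac);
            double sd = std::sqrt(2.0 * Dp * dt);
            double nx = px + dt * d2_slope(px, I1, I2, Dmac) + sd * norm_rand();
            P.x[k] = reflect_into(nx, I1, b, &reflections);
            if (dim == 3) {
                P.y[k] = reflect_into(P.y[k] + sd * norm_rand(), 0.0, cy, 0);
                P.z[k] = reflect_into(P.z[k] + sd * norm_rand(), 0.0, cz, 0);
            }
        }
        // pure-Brownian-region reactions, [I2, b] only
        if (pkill > 0.0) {
            for (size_t k = 0; k < P.x.size(); ++k)
                if (P.alive[k] && P.x[k] >= I2 && unif_rand() < pkill) P.kill((int)k);
        }
        if (rho > 0.0 && Plambda > 0.0) {
            pure.clear();
            for (size_t k = 0; k < P.x.size(); ++k)
                if (P.alive[k] && P.x[k] >= I2) pure.push_back((int)k);
            pairs.clear();
            double rho2 = rho * rho;
            for (size_t ii = 0; ii + 1 < pure.size(); ++ii) {
                for (size_t jj = ii + 1; jj < pure.size(); ++jj) {
                    int ki = pure[ii], kj = pure[jj];
                    double ddx = P.x[ki] - P.x[kj];
                    double d2 = ddx * ddx;
                    if (dim == 3) {
                        double ddy = P.y[ki] - P.y[kj], ddz = P.z[ki] - P.z[kj];
                        d2 += ddy * ddy + ddz * ddz;
                    }
                    if (d2 < rho2) pairs.push_back(std::make_pair(ki, kj));
                }
            }
            for (int ii = (int)pairs.size() - 1; ii > 0; --ii) {  // randomise order
                int jj = (int)(unif_rand() * (ii + 1));
                if (jj > ii) jj = ii;
                std::swap(pairs[ii], pairs[jj]);
            }
            for (size_t ii = 0; ii < pairs.size(); ++ii) {
                int ki = pairs[ii].first, kj = pairs[ii].second;
                if (P.alive[ki] && P.alive[kj] && unif_rand() < Plambda) {
                    P.kill(ki); P.kill(kj);
                }
            }
        }
        if (br_k2 > 0.0) {
            int nnew = (int)R::rpois(br_k2 * Vb * dt);
            for (int r = 0; r < nnew; ++r)
                P.addParticle(I2 + unif_rand() * (b - I2),
                              dim == 3 ? unif_rand() * cy : 0.0,
                              dim == 3 ? unif_rand() * cz : 0.0);
        }
        // (3) rebin: blending counts from the particle histogram
        for (int i = 0; i < n2; ++i) R.C[nc + i] = 0.0;
        for (size_t k = 0; k < P.x.size(); ++k) {
            if (!P.alive[k]) continue;
            double px = P.x[k];
            if (px >= I1 && px < I2) {
                int bi = (int)std::floor((px - I1) / h);
                if (bi >= n2) bi = n2 - 1;
                R.C[nc + bi] += 1.0;
            }
        }
        R.recompute();
        P.compact();
        t += dt;
    }
    NumericMatrix pos(P.nAlive, dim == 3 ? 3 : 1);
    for (int k = 0; k < P.nAlive; ++k) {
        pos(k, 0) = P.x[k];
        if (dim == 3) { pos(k, 1) = P.y[k]; pos(k, 2) = P.z[k]; }
    }
    return List::create(_["C"] = wrap(R.C), _["pos"] = pos,
                        _["reflections"] = reflections);
}

// ---------------------------------------------------------------------------
// Stand-alone Brownian simulation with constant diffusivity on [lo, hi]
// (cross-section [0,cy] x [0,cz] in 3D), reflecting boundaries, first-order
// decay, zeroth-order production and lambda-rho pair annihilation.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_brownian_run(NumericMatrix pos0, double lo, double hi,
                      double cy, double cz, int dim, double D,
                      double mu, double k2, double rho, double Plambda,
                      double dt, int nsteps) {
    ParticleStore P;
    P.dim = dim;
    P.nAlive = 0;
    for (int k = 0; k < pos0.nrow(); ++k)
        P.addParticle(pos0(k, 0),
                      dim == 3 ? pos0(k, 1) : 0.0,
                      dim == 3 ? pos0(k, 2) : 0.0);
    double Vol = (hi - lo) * (dim == 3 ? cy * cz : 1.0);
    double sd = std::sqrt(2.0 * D * dt);
    double pkill = mu > 0.0 ? 1.0 - std::exp(-mu * dt) : 0.0;
    std::vector<std::pair<int, int> > pairs;
    for (int s = 0; s < nsteps; ++s) {
        for (size_t k = 0; k < P.x.size(); ++k) {
            if (!P.alive[k]) continue;
            P.x[k] = reflect_into(P.x[k] + sd * norm_rand(), lo, hi, 0);
            if (dim == 3) {
                P.y[k] = reflect_into(P.y[k] + sd * norm_rand(), 0.0, cy, 0);
                P.z[k] = reflect_into(P.z[k] + sd * norm_rand(), 0.0, cz, 0);
            }
        }
        if (pkill > 0.0) {
            for (size_t k = 0; k < P.x.size(); ++k)
                if (P.alive[k] && unif_rand() < pkill) P.kill((int)k);
        }
        if (rho > 0.0 && Plambda > 0.0) {
            pairs.clear();
            double rho2 = rho * rho;
            for (size_t ki = 0; ki + 1 < P.x.size(); ++ki) {
                if (!P.alive[ki]) continue;
                for (size_t kj = ki + 1; kj < P.x.size(); ++kj) {
                    if (!P.alive[kj]) continue;
                    double ddx = P.x[ki] - P.x[kj];
                    double d2 = ddx * ddx;
                    if (dim == 3) {
                        double ddy = P.y[ki] - P.y[kj], ddz = P.z[ki] - P.z[kj];
                        d2 += ddy * ddy + ddz * ddz;
                    }
                    if (d2 < rho2) pairs.push_back(std::make_pair((int)ki, (int)kj));
                }
            }
            for (int ii = (int)pairs.size() - 1; ii > 0; --ii) {
                int jj = (int)(unif_rand() * (ii + 1));
                if (jj > ii) jj = ii;
                std::swap(pairs[ii], pairs[jj]);
            }
            for (size_t ii = 0; ii < pairs.size(); ++ii) {
                int ki = pairs[ii].first, kj = pairs[ii].second;
                if (P.alive[ki] && P.alive[kj] && unif_rand() < Plambda) {
                    P.kill(ki); P.kill(kj);
                }
            }
        }
        if (k2 > 0.0) {
            int nnew = (int)R::rpois(k2 * Vol * dt);
            for (int r = 0; r < nnew; ++r)
                P.addParticle(lo + unif_rand() * (hi - lo),
                              dim == 3 ? unif_rand() * cy : 0.0,
                              dim == 3 ? unif_rand() * cz : 0.0);
        }
        if ((s & 0xFF) == 0) P.compact();
    }
    P.compact();
    NumericMatrix pos(P.nAlive, dim == 3 ? 3 : 1);
    for (int k = 0; k < P.nAlive; ++k) {
        pos(k, 0) = P.x[k];
        if (dim == 3) { pos(k, 1) = P.y[k]; pos(k, 2) = P.z[k]; }
    }
    return List::create(_["pos"] = pos);
}
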