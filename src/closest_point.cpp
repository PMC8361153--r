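#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact closest point on a triangle (Ericson, Real-Time Collision Detection,
// ch. 5.1.5), returning the point and its barycentric coordinates w.r.t.
// (a, b, c). Barycentric zeros are exact for edge/vertex regions, which the
// R side uses to classify boundary contacts.
static inline double dot3(const double* u, const double* v) {
    return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
}

static void closest_pt_triangle(const double* p, const double* a,
                                const double* b, const double* c,
                                double* out, double* bary) {
    double ab[3], ac[3], ap[3];
    for (int i = 0; i < 3; ++i) {
        ab[i] = b[i] - a[i];
        ac[i] = c[i] - a[i];
        ap[i] = p[i] - a[i];
    }
    double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
    if (d1 <= 0.0 && d2 <= 0.0) {  // vertex a
        for (int i = 0; i < 3; ++i) out[i] = a[i];
        bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
        return;
    }
    double bp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
    if (d3 >= 0.0 && d4 <= d3) {  // vertex b
        for (int i = 0; i < 3; ++i) out[i] = b[i];
        bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
        return;
    }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {  // edge ab
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
        bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
        return;
    }
    double cp[3];
    for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
    double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
    if (d6 >= 0.0 && d5 <= d6) {  // vertex c
        for (int i = 0; i < 3; ++i) out[i] = c[i];
        bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
        return;
    }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {  // edge ac
        double w = d2 / (d2 - d6);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
        bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
        return;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {  // edge bc
        double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
        bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
        return;
    }
    double denom = 1.0 / (va + vb + vc);  // face interior
    double v = vb * denom, w = vc * denom;
    for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
    bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

// Exact closest point on a triangulated surface for each query point.
// Pruning is exact: a triangle whose centroid distance minus circumradius
// bound exceeds the best distance so far cannot contain a closer point.
// F is 0-based. Returns distances, closest points, supporting face (0-based)
// and barycentric coordinates.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
    const int nq = Q.nrow(), nf = F.nrow();
    if (nf == 0) stop("mesh has no faces");

    // cache triangle vertices, centroids and bounding radii
    std::vector<double> ta(3 * nf), tb(3 * nf), tc(3 * nf);
    std::vector<double> cen(3 * nf), rad(nf);
    for (int t = 0; t < nf; ++t) {
        const int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
        for (int i = 0; i < 3; ++i) {
            ta[3 * t + i] = V(ia, i);
            tb[3 * t + i] = V(ib, i);
            tc[3 * t + i] = V(ic, i);
            cen[3 * t + i] =
                (ta[3 * t + i] + tb[3 * t + i] + tc[3 * t + i]) / 3.0;
        }
        double r2 = 0.0;
        for (int k = 0; k < 3; ++k) {
            const double* pv = (k == 0) ? &ta[3 * t]
                               : (k == 1) ? &tb[3 * t] : &tc[3 * t];
            double d2 = 0.0;
            for (int i = 0; i < 3; ++i) {
                double d = pv[i] - cen[3 * t + i];
                d2 += d * d;
            }
            if (d2 > r2) r2 = d2;
        }
        rad[t] = std::sqrt(r2);
    }

    NumericVector dist(nq);
    NumericMatrix pts(nq, 3), bar(nq, 3);
    IntegerVector face(nq);
    std::vector<double> cd(nf);

    for (int q = 0; q < nq; ++q) {
        double p[3] = {Q(q, 0), Q(q, 1), Q(q, 2)};
        int t0 = 0;
        double cmin = std::numeric_limits<double>::infinity();
        for (int t = 0; t < nf; ++t) {
            double d2 = 0.0;
            for (int i = 0; i < 3; ++i) {
                double d = p[i] - cen[3 * t + i];
                d2 += d * d;
            }
            cd[t] = std::sqrt(d2);
            if (cd[t] < cmin) { cmin = cd[t]; t0 = t; }
        }
        double bestpt[3], bestbar[3], tmp[3], tmb[3];
        closest_pt_triangle(p, &ta[3 * t0], &tb[3 * t0], &tc[3 * t0],
                            bestpt, bestbar);
        double best2 = 0.0;
        for (int i = 0; i < 3; ++i) {
            double d = p[i] - bestpt[i];
            best2 += d * d;
        }
        double best = std::sqrt(best2);
        int bestt = t0;
        for (int t = 0; t < nf; ++t) {
            if (t == t0) continue;
            if (cd[t] - rad[t] >= best) continue;
            closest_pt_triangle(p, &ta[3 * t], &tb[3 * t], &tc[3 * t],
                                tmp, tmb);
            double d2 = 0.0;
            for (int i = 0; i < 3; ++i) {
                double d = p[i] - tmp[i];
                d2 += d * d;
            }
            double d = std::sqrt(d2);
            if (d < best) {
                best = d;
                bestt = t;
                for (int i = 0; i < 3; ++i) {
                    bestpt[i] = tmp[i];
                    bestbar[i] = tmb[i];
                }
            }
        }
        dist[q] = best;
        face[q] = bestt;
        for (int i = 0; i < 3; ++i) {
            pts(q, i) = bestpt[i];
            bar(q, i) = bestbar[i];
        }
    }
    return List::create(_["dist"] = dist, _["point"] = pts,
                        _["face"] = face, _["bary"] = bar);
}

// Nearest vertex (brute force, exact). Returns 0-based indices and distances.
// [[Rcpp::export]]
List cpp_nearest_vertex(NumericMatrix Q, NumericMatrix V) {
    const int nq = Q.nrow(), nv = V.nrow();
    if (nv == 0) stop("no vertices");
    IntegerVector idx(nq);
    NumericVector dist(nq);
    for (int q = 0; q < nq; ++q) {
        double best = std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int v = 0; v < nv; ++v) {
            double d2 = 0.0;
            for (int i = 0; i < 3; ++i) {
                double d = Q(q, i) - V(v, i);
                d2 += d * d;
            }
            if (d2 < best) { best = d2; bi = v; }
        }
        idx[q] = bi;
        dist[q] = std::sqrt(best);
    }
    return List::create(_["index"] = idx, _["dist"] = dist);
}
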