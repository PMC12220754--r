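"""Independent high-precision oracle for the disproportionality statistics.

Reads a CSV with header a,b,c,d and writes a CSV of every statistic,
evaluated with mpmath at 50 significant digits straight from the published
closed-form definitions. Used by the test suite as an arithmetic referee for
the R implementation; shares no code with it.

Usage: python signal_oracle.py tables.csv > stats.csv
"""
import csv
import sys

from mpmath import mp, mpf, e, log, sqrt

mp.dps = 50
Z = mpf("1.96")
A1 = B1 = G11 = mpf(1)
AL = BE = mpf(2)

COLS = ["ror", "ror_ci_low", "ror_ci_high", "prr", "prr_ci_low",
        "prr_ci_high", "chi2", "ic", "e_ic", "v_ic", "ic_minus_2sd",
        "ebgm", "ebgm05", "ebgm95"]


def stats(a, b, c, d):
    n = a + b + c + d
    out = {}
    if min(a, b, c, d) > 0:
        ror = a * d / (b * c)
        se = sqrt(1 / a + 1 / b + 1 / c + 1 / d)
        out["ror"] = ror
        out["ror_ci_low"] = ror * e ** (-Z * se)
        out["ror_ci_high"] = ror * e ** (Z * se)
    if a + b > 0 and c > 0:
        prr = (a / (a + b)) / (c / (c + d))
        out["prr"] = prr
        if a > 0:
            se = sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
            out["prr_ci_low"] = prr * e ** (-Z * se)
            out["prr_ci_high"] = prr * e ** (Z * se)
    if min(a + b, a + c, c + d, b + d) > 0:
        out["chi2"] = (a * d - b * c) ** 2 * n / ((a + b) * (a + c) * (c + d) * (b + d))
    if a > 0:
        out["ic"] = log(a * n / ((a + b) * (a + c)), 2)
    g = G11 * (n + AL) * (n + BE) / ((a + b + A1) * (a + c + B1))
    out["e_ic"] = log((a + G11) * (n + AL) * (n + BE)
                      / ((n + g) * (a + b + A1) * (a + c + B1)), 2)
    out["v_ic"] = (1 / log(2) ** 2) * (
        (n - a + g - G11) / ((a + G11) * (1 + n + g))
        + (n - (a + b) + AL - A1) / ((a + b + A1) * (1 + n + AL))
        + (n - (a + c) + BE - B1) / ((a + c + B1) * (1 + n + BE)))
    out["ic_minus_2sd"] = out["e_ic"] - 2 * sqrt(out["v_ic"])
    if a + b > 0 and a + c > 0:
        ebgm = a * n / ((a + c) * (a + b))
        out["ebgm"] = ebgm
        if min(a, b, c, d) > 0:
            se = sqrt(1 / a + 1 / b + 1 / c + 1 / d)
            out["ebgm05"] = ebgm * e ** (-Z * se)
            out["ebgm95"] = ebgm * e ** (Z * se)
    return out


def main():
    with open(sys.argv[1], newline="") as fh:
        rows = list(csv.DictReader(fh))
    w = csv.writer(sys.stdout)
    w.writerow(COLS)
    for r in rows:
        s = stats(*(mpf(r[k]) for k in "abcd"))
        w.writerow([mp.nstr(s[k], 22) if k in s else "NA" for k in COLS])


if __name__ == "__main__":
    main()
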