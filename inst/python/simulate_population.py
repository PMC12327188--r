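"""Coalescent population simulator bridge.

Reads a JSON config, simulates phased haplotypes per chromosome with
msprime, and writes one compact text file per chromosome:
one line per segregating site, "<pos_bp>\t<allele digits over haplotypes>".
Haplotype columns are sample-major (sample 1 hap 1, sample 1 hap 2, ...).
"""
import json
import sys

import msprime
import numpy as np


def build_demography(cfg):
    d = msprime.Demography()
    kind = cfg.get("type", "constant")
    if kind == "constant":
        d.add_population(name="A", initial_size=cfg["ne"])
    elif kind == "growth":
        ne0 = cfg["ne_ancestral"]
        ne1 = cfg["ne_present"]
        t = cfg["t_growth"]
        rate = np.log(ne1 / ne0) / t
        d.add_population(name="A", initial_size=ne1, growth_rate=rate)
        d.add_population_parameters_change(
            time=t, initial_size=ne0, growth_rate=0, population="A")
        if "ne_deep" in cfg and "t_deep" in cfg:
            d.add_population_parameters_change(
                time=cfg["t_deep"], initial_size=cfg["ne_deep"],
                growth_rate=0, population="A")
    else:
        raise ValueError(f"unknown demography type {kind!r}")
    return d


def main():
    with open(sys.argv[1]) as fh:
        cfg = json.load(fh)
    out_dir = sys.argv[2]
    demog = build_demography(cfg["demography"])
    n = int(cfg["n"])
    seed = int(cfg["seed"])
    files = []
    for k, length_cm in enumerate(cfg["chromosomes"], start=1):
        bp = length_cm / cfg["cm_per_mb"] * 1e6
        s = (seed * 1000 + 2 * k) % 2147483646 + 1
        ts = msprime.sim_ancestry(
            samples=n, demography=demog, sequence_length=bp,
            recombination_rate=cfg["recombination_rate"], random_seed=s)
        ts = msprime.sim_mutations(
            ts, rate=cfg["mutation_rate"], random_seed=s + 1)
        path = f"{out_dir}/chr{k}.haps.txt"
        G = ts.genotype_matrix()
        np.minimum(G, 9, out=G)
        positions = (ts.tables.sites.position.astype(np.int64) + 1)
        body = (G + 48).astype(np.uint8)
        with open(path, "wb") as out:
            for j in range(body.shape[0]):
                out.write(str(int(positions[j])).encode())
                out.write(b"\t")
                out.write(body[j].tobytes())
                out.write(b"\n")
        files.append(path)
    with open(f"{out_dir}/manifest.json", "w") as fh:
        json.dump({"n": n, "files": files,
                   "chromosomes": cfg["chromosomes"]}, fh)


if __name__ == "__main__":
    main()
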