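#!/usr/bin/env bash
# Regenerate the assembler-dependent part of the benchmark: assemble the
# simulated reads with real metagenome assemblers and score recovery of the
# planted transfers from the resulting contigs.
#
# This harness is NOT exercised by the test suite: the recovered-transfer
# counts depend on the assembler and its version (IDBA_UD 1.1.1 and
# metaSPAdes 3.9.0 were used originally, with several k-mer ranges), so they
# are not reproducible from this package alone. Requirements:
#   - idba_ud (fq2fa helper) and/or metaspades.py on PATH
#   - blastn (BLAST+) on PATH
#   - the hgtbench R package installed
#
# Usage: scripts/assembly_harness.sh <workdir> <seed> <mutation-level>
set -euo pipefail

WORK=${1:?workdir}; SEED=${2:-1}; LEVEL=${3:-10}
CLI="$(Rscript -e 'cat(system.file("cli", "hgtbench", package = "hgtbench"))')"

mkdir -p "$WORK"
Rscript "$CLI" fixtures --out "$WORK/fixtures" --seed "$SEED"
Rscript "$CLI" mutate --genes "$WORK/fixtures/donor_genes.fasta" \
  --mutation-level "$LEVEL" --ratio 1:0:1:1 --seed "$SEED" --out "$WORK/mut"
Rscript "$CLI" insert --genes "$WORK/mut/mutated_genes.fasta" \
  --recipients "$WORK/fixtures" --flank TAGATGAGTGATTAGTTAGTTA \
  --mode uniform --seed "$SEED" --out "$WORK/ins"

# community = modified recipients; simulate error-free 2x100 bp, 250 bp insert
mkdir -p "$WORK/community"
cp "$WORK/ins/"*_modified.fasta "$WORK/community/"
Rscript "$CLI" simulate-reads --community "$WORK/community" \
  --n-pairs 2000000 --read-length 100 --insert-size 250 \
  --seed "$SEED" --out "$WORK/reads"

# assemble (pick whichever assembler is installed)
if command -v metaspades.py >/dev/null; then
  metaspades.py -1 "$WORK/reads/reads_R1.fastq" -2 "$WORK/reads/reads_R2.fastq" \
    -o "$WORK/asm_metaspades" -k 21,33,55
  CONTIGS="$WORK/asm_metaspades/contigs.fasta"
elif command -v idba_ud >/dev/null; then
  fq2fa --merge "$WORK/reads/reads_R1.fastq" "$WORK/reads/reads_R2.fastq" \
    "$WORK/reads/merged.fa"
  idba_ud -r "$WORK/reads/merged.fa" -o "$WORK/asm_idba"
  CONTIGS="$WORK/asm_idba/contig.fa"
else
  echo "no supported assembler (metaspades.py / idba_ud) on PATH" >&2
  exit 1
fi

# align transfers to contigs and score recovery at 99/99 with >1 kb flanks
makeblastdb -in "$CONTIGS" -dbtype nucl -out "$WORK/contigdb"
blastn -query "$WORK/ins/cassettes.fasta" -db "$WORK/contigdb" \
  -outfmt 6 -out "$WORK/hits.tsv"
Rscript "$CLI" evaluate --insertion-report "$WORK/ins/insertion_report.tsv" \
  --cassettes "$WORK/ins/cassettes.fasta" --contigs "$CONTIGS" \
  --recipients "$WORK/fixtures" --hits "$WORK/hits.tsv" --out "$WORK/eval"

cat "$WORK/eval/recovery_summary.tsv"
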