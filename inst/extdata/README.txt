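Drop-in location for the deposited supplementary character matrices of
the allodaposuchid postcranial-signal study (not redistributable with
the package):

  S1_dataset.txt  - full 108 OTU x 189 character matrix (TNT text)
  S2_dataset.txt  - the same matrix with postcranial characters set to
                    missing in the allodaposuchid OTUs
  S3_dataset.tnt  - the revised-codification matrix

With these files present, the acceptance blocks in
tests/testthat/test-acceptance.R verify the published matrix
dimensions and partition sizes, tree lengths (797/798/805/783),
ensemble indices (CI 0.29, RI 0.77), placement/monophyly claims and
synapomorphy lists. Without them those blocks fail with a pointer to
this file.
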