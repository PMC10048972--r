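term_id	module
hsa04001	inflammation
hsa04002	inflammation
hsa04003	inflammation
hsa04004	inflammation
hsa04005	inflammation
hsa04006	inflammation
hsa04007	inflammation
hsa04008	inflammation
hsa04009	inflammation
hsa04010	inflammation
hsa04011	inflammation
hsa04012	inflammation
hsa04013	inflammation
hsa04014	inflammation
hsa04015	metabolism
hsa04016	metabolism
hsa04017	metabolism
hsa04018	metabolism
hsa04019	metabolism
hsa04020	metabolism
hsa04021	metabolism
hsa04022	metabolism
hsa04023	metabolism
hsa04024	metabolism
hsa04025	other
hsa04026	other
hsa04027	other
hsa04028	other
hsa04029	other
hsa04030	other
hsa04031	other
hsa04032	other
hsa04033	other
hsa04034	other
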