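chrom	start	end	n_snps
OCU2	7292553	7492553	1
OCU2	8691893	8891893	1
OCU2	10401993	10691957	2
OCU2	11278860	11478860	1
OCU2	13286997	13486997	1
OCU2	13388329	13588329	1
OCU2	13670022	13985731	4
OCU2	14118502	14318502	1
OCU2	14281825	14488318	2
OCU2	15440704	15640704	1
OCU2	19248590	19448590	1
OCU2	19419932	19619932	1
OCU2	21666582	21866582	1
OCU2	21861157	22251345	7
OCU2	22187659	22387659	1
OCU2	22452417	22774072	9
OCU2	24305104	24505104	1
OCU2	31343212	31566952	2
OCU2	58161249	58361249	1
OCU2	65206234	65496063	2
OCU4	19021968	19221968	1
OCU9	35423218	35623218	1
OCU11	64851640	65051640	1
OCU19	52059278	52259278	1
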