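# SYNTHETIC RLBP1 reference scheme.
#
# The ten residues critical for retinoid binding by RLBP1/CRALBP
# (identified by site-directed mutagenesis) sit at their literature
# positions — W166, Y180, F198, C199, M209, Q211, M223, V224, M226,
# W245 — but the 317-aa background sequence is SYNTHETIC (deterministic
# random draw), not the human protein.  Conservation tallies against
# this scheme are positionally faithful only at the ten critical sites.
# To profile real CRAL_TRIO proteins in literature numbering, build a
# scheme on the genuine human RLBP1 sequence (UniProt P12271) and pass
# its config path instead.
scheme_id	rlbp1_synthetic
reference	DFCNASEHAETVFEFIEYVFGLTSMECRLMTFASAVKQRACAPLNTPESPGNCHRASVRLFVCGSLHGHVPLRLCQCAWMEHLDSDHFHYKSAESQKEFKNWTCGIFWDKIGKDQTVAHSKMTQTFNTRDNDEENYVPRMEKPKSCLWHSDSSDMKVRYPWQWVFWGMRVDVHECRWCHYACGFRWFHFVCDESTQIFCYYDIMHKLLMMQEWNQHELGQCLMVTMGNFNEQDHPPALYYITMGWPHYHYIFHTMHCTSNYHLTWDMIMYLTFWGNVLMHLSDEYCGPGIIQDHSFFYPKKECCISAHRNRFFFDPG
site	W166=166:W:rlbp1_critical
site	Y180=180:Y:rlbp1_critical
site	F198=198:F:rlbp1_critical
site	C199=199:C:rlbp1_critical
site	M209=209:M:rlbp1_critical
site	Q211=211:Q:rlbp1_critical
site	M223=223:M:rlbp1_critical
site	V224=224:V:rlbp1_critical
site	M226=226:M:rlbp1_critical
site	W245=245:W:rlbp1_critical
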