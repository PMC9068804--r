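vid	grch38_name	grch37_name	coding_name	intron	n_hcm	n_other	hcm_pct	spliceai_delta	defect_class	trf_label
v1	g.47351515C>T	g.47373066C>T	c.26-10G>A	1	2	1	0.021	0.39	E2sk	In-frame (del 89 aa)
v2	g.47350117G>A	g.47371668G>A	c.407-5C>T	3	2	2	0.021	0.18	E4sk	In-frame (del 33 aa)
v3	g.47350009C>G	g.47371560C>G	c.505+5G>C	4	1	0	0.010	0.86	E4tr	Frameshift-PTC
v4	g.47350008A>C	g.47371559A>C	c.505+6T>G	4	0	0	0.000	0.85	E4sk	In-frame (del 33 aa)
v5	g.47349769C>G	g.47371320C>G	c.654+5G>C	5	1	0	0.010	0.62	E5tr	In-frame (del 16 aa)
v6	g.47349769C>T	g.47371320C>T	c.654+5G>A	5	1	0	0.010	0.50	E5sk	Frameshift-PTC
v7	g.47348566T>C	g.47370117T>C	c.655-25A>G	5	1	0	0.010	0.19	E6sk	Frameshift-PTC
v8	g.47347854C>A	g.47369405C>A	c.821+3G>T	7	1	0	0.010	0.71	E7sk	Frameshift-PTC
v9	g.47347852C>T	g.47369403C>T	c.821+5G>A	7	2	0	0.021	0.86	E7sk	Frameshift-PTC
v10	g.47347065C>T	g.47368616C>T	c.906-36G>A	9	9	0	0.094	0.91	pRi9/E10ext	Frameshift-PTC
v11	g.47347037A>G	g.47368588A>G	c.906-8T>C	9	0	0	0.000	0.12	E10sk	In-frame (ins 1 aa, del 2 aa)
v12	g.47346623T>C	g.47368174T>C	c.926+4A>G	11	0	0	0.000	0.40	E11sk	In-frame (ins 1 aa, del 7 aa)
v13	g.47346380G>T	g.47367931G>T	c.927-10C>A	11	0	0	0.000	0.45	E12sk	Frameshift-PTC
v14	g.47346379C>T	g.47367930C>T	c.927-9G>A	11	12	1	0.125	0.28	E12sk	Frameshift-PTC
v15	g.47346378C>T	g.47367929C>T	c.927-8G>A	11	1	0	0.010	0.11	pRi11/E12ext	Frameshift-PTC
v16	g.47345754G>A	g.47367305G>A	c.1090+453C>T	12	0	0	0.000	0.56	crypEins in i12	Frameshift-PTC
v17	g.47344199T>G	g.47365750T>G	c.1091-575A>C	12	0	0	0.000	0.38	crypEins in i12	Frameshift-PTC
v18	g.47343342C>T	g.47364893C>T	c.1224-80G>A	13	6	0	0.175	0.94	pRi13/E14ext	In-frame (ins 26 aa)
v19	g.47343314C>T	g.47364865C>T	c.1224-52G>A	13	12	1	0.125	0.99	pRi13/E14ext	Frameshift-PTC
v20	g.47343283T>C	g.47364834T>C	c.1224-21A>G	13	0	0	0.000	0.90	pRi13/E14ext	Frameshift-PTC
v21	g.47343281C>T	g.47364832C>T	c.1224-19G>A	13	15	0	0.156	0.81	pRi13/E14ext	Frameshift-PTC
v22	g.47343159G>T	g.47364710G>T	c.1227-14C>A	14	0	0	0.000	0.43	E15sk	Frameshift-PTC
v23	g.47343158C>T	g.47364709C>T	c.1227-13G>A	14	8	0	0.083	0.98	pRi14/E15ext	Frameshift-PTC
v24	g.47343154G>T	g.47364705G>T	c.1227-9C>A	14	0	0	0.000	0.08	E15sk	Frameshift-PTC
v25	g.47342827C>G	g.47364378C>G	c.1457+3G>C	16	0	0	0.000	0.25	E16sk	Frameshift-PTC
v26	g.47342825C>G	g.47364376C>G	c.1457+5G>C	16	1	0	0.010	0.93	E16sk	Frameshift-PTC
v27	g.47342574T>A	g.47364125T>A	c.1624+4A>T	17	3	0	0.031	0.16	E17sk	Stop gain-PTC
v28	g.47342163G>T	g.47363714G>T	c.1625-7C>A	17	0	0	0.000	0.11	E18sk	Frameshift-PTC
v29	g.47341986C>T	g.47363537C>T	c.1790+5G>A	18	0	0	0.000	0.89	E18sk	Frameshift-PTC
v30	g.47341133C>T	g.47362684C>T	c.1897+5G>A	19	0	0	0.000	0.77	E19sk	Frameshift-PTC
v31	g.47341055T>C	g.47362606T>C	c.1898-23A>G	19	4	0	0.042	0.04	cRi19	Frameshift-PTC
v32	g.47340403G>A	g.47361954G>A	c.1927+600C>T	20	7	1	0.204	0.13	crypEins in i20	Frameshift-PTC
v33	g.47340359C>A	g.47361910C>A	c.1928-569G>T	20	0	0	0.000	0.23	crypEins in i20	Frameshift-PTC
v34	g.47338682G>C	g.47360233G>C	c.2149-3C>G	22	1	0	0.010	0.61	E23sk	Frameshift-PTC
v35	g.47338517C>G	g.47360068C>G	c.2308+3G>C	23	0	0	0.000	0.74	E23sk	Frameshift-PTC
v36	g.47337820T>C	g.47359371T>C	c.2309-26A>G	23	0	0	0.000	0.35	E24sk	In-frame (del 35 aa)
v37	g.47337615C>A	g.47359166C>A	c.2414-36G>T	24	0	0	0.000	0.52	pRi24/E25ext	Frameshift-PTC
v38	g.47335212G>C	g.47356763G>C	c.2738-3C>G	26	0	0	0.000	0.61	E27sk	Stop gain-PTC
v39	g.47335037C>A	g.47356588C>A	c.2905+5G>T	27	0	0	0.000	0.96	E27sk	Stop gain-PTC
v40	g.47333552C>T	g.47355103C>T	c.3190+5G>A	29	10	0	0.104	0.85	E29sk	Frameshift-PTC
v41	g.47333189C>A	g.47354740C>A	c.3330+5G>T	30	0	0	0.000	0.25	E30sk	Frameshift-PTC
v42	g.47333189C>G	g.47354740C>G	c.3330+5G>C	30	14	1	0.146	0.30	E30sk	Frameshift-PTC
v43	g.47333189C>T	g.47354740C>T	c.3330+5G>A	30	1	0	0.010	0.25	E30sk	Frameshift-PTC
v44	g.47332999A>C	g.47354550A>C	c.3331-26T>G	30	3	0	0.031	0.16	cRi30	Frameshift-PTC
v45	g.47332705G>C	g.47354256G>C	c.3491-3C>G	31	4	0	0.042	0.90	E32sk	Frameshift-PTC
v46	g.47332270G>C	g.47353821G>C	c.3628-12C>G	32	0	0	0.000	0.95	E33sk	Frameshift-stop loss
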