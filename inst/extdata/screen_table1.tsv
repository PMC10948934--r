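gene	uniprot	line_id	source	suppression	viable
CG8069	A1Z7P3	100778	KK	++	TRUE
CG8069	A1Z7P3	28189	GD	++	TRUE
CG4548	Q9GQN5	101568	KK	++	TRUE
CG4548	Q9GQN5	10618	GD	++	TRUE
CG7961	Q9W0B8	35305	GD	++	TRUE
CG7961	Q9W0B8	35306	GD	+	TRUE
CG7843	Q9V9K7	106344	KK	+	TRUE
CG7843	Q9V9K7	22574	GD	+	TRUE
CG42665	Q9VVC6	105885	KK	+	TRUE
CG42665	Q9VVC6	101144	KK	+	TRUE
CG8092	A0A0B4KER0	28196	GD	+	TRUE
CG8092	A0A0B4KER0	25971	TRiP	+	TRUE
CG42458	Q7KU81	106608	KK	++	TRUE
CG42458	Q7KU81	108072	KK	++	TRUE
CG42522	Q7KTH8	33370	TRiP	++	TRUE
CG1677	Q9W3R9	109697	KK	++	TRUE
CG1677	Q9W3R9	50195	GD	+	TRUE
CG14443	Q9W3Y5	105254	KK	++	TRUE
CG14443	Q9W3Y5	17618	GD	++	TRUE
CG1542	Q9V9Z9	104575	KK	++	TRUE
CG1542	Q9V9Z9	39976	GD	++	TRUE
CG9825	Q9W1Z1	105868	KK	++	TRUE
CG9825	Q9W1Z1	1712	GD	++	TRUE
CG9205	Q9W0K9	107612	KK	+	TRUE
CG9205	Q9W0K9	29079	GD	++	TRUE
CG7971	A8JNI2	101384	KK	++	TRUE
CG7971	A8JNI2	34262	GD	+	TRUE
CG4799	P52295	102627	KK	+	TRUE
CG4799	P52295	32466	GD	++	TRUE
CG9915	A8JV07	103731	KK	++	TRUE
CG13849	Q95WY3	103738	KK	+	TRUE
CG13849	Q95WY3	51775	GD	+	TRUE
CG9181	Q9W0G1	108888	KK	++	TRUE
CG9181	Q9W0G1	37436	GD	++	TRUE
CG4396	Q9VYI0	101508	KK	+	TRUE
CG4396	Q9VYI0	48891	GD	+	TRUE
CG33967	Q9VFG8	106507	KK	++	TRUE
CG33967	Q9VFG8	100765	KK	++	TRUE
CG13176	Q7JW27	39769	GD	++	TRUE
CG13176	Q7JW27	24642	GD	++	TRUE
CG3071	Q9W4Z9	107206	KK	++	TRUE
CG3071	Q9W4Z9	29589	GD	+	TRUE
CG1598	Q7JWD3	110555	KK	+	TRUE
CG1598	Q7JWD3	32391	GD	++	TRUE
CG40218	Q8SXI2	102960	KK	++	TRUE
CG4697	Q9VJR9	34308	GD	++	TRUE
CG4697	Q9VJR9	34307	GD	++	TRUE
CG14444	Q9W3Y6	110729	KK	++	TRUE
CG14444	Q9W3Y6	17622	GD	++	TRUE
CG2890	Q9W2U4	105399	KK	++	TRUE
CG2890	Q9W2U4	25445	GD	++	TRUE
CG7283	Q9VTP4	109345	KK	++	TRUE
CG7283	Q9VTP4	23459	GD	++	TRUE
CG2807	Q9VPR5	110091	KK	+	TRUE
CG2807	Q9VPR5	25162	GD	++	TRUE
CG6538	P41900	110569	KK	+	TRUE
CG6538	P41900	12602	GD	+	TRUE
CG18332	Q8SYG2	101516	KK	+	TRUE
CG18332	Q8SYG2	12821	GD	++	TRUE
CG6379	Q9W4N2	103723	KK	+	TRUE
CG6379	Q9W4N2	29611	GD	++	TRUE
CG1427	Q9VNE3	105727	KK	+	TRUE
CG1427	Q9VNE3	17456	GD	++	TRUE
CG10275	Q9VJ82	106680	KK	++	TRUE
CG10275	Q9VJ82	37283	GD	++	TRUE
CG2790	Q9W0X8	101619	KK	+	TRUE
CG2790	Q9W0X8	20903	GD	+	TRUE
CG10415	O96880	100572	KK	+	TRUE
CG10415	O96880	12592	GD	+	TRUE
CG11228	Q8T0S6	104169	KK	++	TRUE
CG11228	Q8T0S6	7823	GD	+	TRUE
CG1091	Q9VI58	107175	KK	+	TRUE
CG1091	Q9VI58	16088	GD	++	TRUE
CG33106	Q9VCA8	103411	KK	++	TRUE
CG33106	Q9VCA8	33394	GD	+	TRUE
CG33208	Q86BA1	105837	KK	+	TRUE
CG33208	Q86BA1	25371	GD	+	TRUE
CG15224	P08182	106845	KK	+	TRUE
CG15224	P08182	32377	GD	+	TRUE
CG17593	Q9VQR9	106469	KK	++	TRUE
CG17593	Q9VQR9	13029	GD	++	TRUE
CG33017	A1ZAC8	103968	KK	+	TRUE
CG33017	A1ZAC8	40022	GD	+	TRUE
CG4299	P53997	108987	KK	+	TRUE
CG4299	P53997	77433	TRiP	+	TRUE
CG7207	Q9Y128	103563	KK	++	TRUE
CG7207	Q9Y128	27914	GD	+	TRUE
CG4202	Q9I7W5	103352	KK	++	TRUE
CG4202	Q9I7W5	49946	GD	+	TRUE
CG9977	Q9VZX9	106749	KK	++	TRUE
CG9977	Q9VZX9	36193	GD	++	TRUE
CG32847	Q8IQM1	104294	KK	++	TRUE
CG32847	Q8IQM1	48423	GD	++	TRUE
CG7839	Q9VTE6	105979	KK	+	TRUE
CG7839	Q9VTE6	12691	GD	+	TRUE
CG7483	Q9VHS8	108580	KK	++	TRUE
CG7483	Q9VHS8	32444	TRiP	+	TRUE
CG9556	Q94899	48044	GD	++	TRUE
CG9556	Q94899	28908	TRiP	++	TRUE
CG3825	Q9W1E4	107545	KK	+	TRUE
CG3825	Q9W1E4	33011	TRiP	+	TRUE
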