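gene	line_id	norpa	erg
CG8069	100778	FALSE	normal
CG8069	28189	FALSE	normal
CG4548	101568	TRUE	normal
CG4548	10618	TRUE	normal
CG7961	35305	FALSE	normal
CG7961	35306	FALSE	normal
CG7843	106344	FALSE	rough_eye
CG7843	22574	FALSE	lower
CG42665	105885	FALSE	normal
CG42665	101144	FALSE	normal
CG8092	28196	FALSE	normal
CG8092	25971	FALSE	normal
CG42458	106608	TRUE	normal
CG42458	108072	TRUE	normal
CG42522	33370	FALSE	normal
CG1677	109697	TRUE	normal
CG1677	50195	TRUE	normal
CG14443	105254	TRUE	normal
CG14443	17618	TRUE	normal
CG1542	104575	TRUE	normal
CG1542	39976	TRUE	normal
CG9825	105868	FALSE	normal
CG9825	1712	FALSE	normal
CG9205	107612	FALSE	lower
CG9205	29079	FALSE	lower
CG7971	101384	TRUE	normal
CG7971	34262	TRUE	normal
CG4799	102627	FALSE	normal
CG4799	32466	FALSE	normal
CG9915	103731	TRUE	normal
CG13849	103738	TRUE	normal
CG13849	51775	TRUE	normal
CG9181	108888	FALSE	normal
CG9181	37436	FALSE	normal
CG4396	101508	FALSE	normal
CG4396	48891	FALSE	normal
CG33967	106507	FALSE	normal
CG33967	100765	FALSE	normal
CG13176	39769	FALSE	normal
CG13176	24642	FALSE	normal
CG3071	107206	FALSE	higher
CG3071	29589	FALSE	higher
CG1598	110555	FALSE	normal
CG1598	32391	FALSE	normal
CG40218	102960	FALSE	lower
CG4697	34308	FALSE	normal
CG4697	34307	FALSE	normal
CG14444	110729	FALSE	lower
CG14444	17622	FALSE	lower
CG2890	105399	FALSE	normal
CG2890	25445	FALSE	normal
CG7283	109345	TRUE	rough_eye
CG7283	23459	TRUE	rough_eye
CG2807	110091	TRUE	rough_eye
CG2807	25162	TRUE	rough_eye
CG6538	110569	TRUE	normal
CG6538	12602	TRUE	normal
CG18332	101516	FALSE	normal
CG18332	12821	FALSE	normal
CG6379	103723	TRUE	rough_eye
CG6379	29611	TRUE	lower
CG1427	105727	FALSE	rough_eye
CG1427	17456	FALSE	lower
CG10275	106680	FALSE	normal
CG10275	37283	FALSE	normal
CG2790	101619	FALSE	normal
CG2790	20903	FALSE	normal
CG10415	100572	FALSE	normal
CG10415	12592	FALSE	normal
CG11228	104169	FALSE	normal
CG11228	7823	FALSE	normal
CG1091	107175	FALSE	normal
CG1091	16088	FALSE	normal
CG33106	103411	FALSE	normal
CG33106	33394	FALSE	normal
CG33208	105837	FALSE	normal
CG33208	25371	FALSE	normal
CG15224	106845	FALSE	normal
CG15224	32377	FALSE	normal
CG17593	106469	FALSE	normal
CG17593	13029	FALSE	normal
CG33017	103968	FALSE	normal
CG33017	40022	FALSE	normal
CG4299	108987	FALSE	lower
CG4299	77433	FALSE	lower
CG7207	103563	FALSE	lower
CG7207	27914	FALSE	lower
CG4202	103352	TRUE	normal
CG4202	49946	TRUE	normal
CG9977	106749	FALSE	normal
CG9977	36193	FALSE	normal
CG32847	104294	FALSE	normal
CG32847	48423	FALSE	normal
CG7839	105979	FALSE	normal
CG7839	12691	FALSE	normal
CG7483	108580	FALSE	rough_eye
CG7483	32444	FALSE	lower
CG9556	48044	FALSE	normal
CG9556	28908	FALSE	normal
CG3825	107545	FALSE	normal
CG3825	33011	FALSE	normal
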